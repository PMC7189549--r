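# plaquescope

Quantification of amyloid-beta (Aβ) pathology in whole-slide images of
immunostained brain tissue.

Neuropathologists grade Aβ burden with semi-quantitative CERAD-style
categories (*none* < *sparse* < *moderate* < *frequent*) assigned by
eye. `plaquescope` implements the quantitative counterpart: a compact
convolutional classifier is slid across the slide at a fixed stride,
producing a per-class **confidence heatmap** for three Aβ morphologies
— cored plaques, diffuse plaques, and cerebral amyloid angiopathy
(CAA) — and each heatmap is reduced to a **CNN score**

```
CNN score = (# blobs after threshold → open/close → connected-component labeling) / region area [px]
```

computed over the whole tissue, its gray-matter subset (annotation
masks or polygons), or fixed ~4 mm² CERAD-style fields of view
(251 heatmap px ≈ a 10× objective field at 16 WSI px/heatmap px and
0.5 µm/px). Cohort-level functions compare scores against ordinal
ratings (Spearman), diagnosis groups (t-test, ANOVA + Tukey HSD,
Kruskal–Wallis), and NIA-Reagan likelihood levels.

The package is aimed at digital-pathology researchers who want a
tested, self-contained re-implementation of this scoring pipeline: a
synthetic slide/cohort generator with exact ground truth makes every
stage verifiable without institutional data, and the CNN (six 3×3
conv + max-pool blocks, dense 512 and 100, three sigmoid outputs) is
built, trained, and applied entirely within the package (RcppArmadillo
numerics — no external deep-learning framework).

## Worked example

Score a synthetic slide's heatmap, restrict to gray matter, and pick
the densest fields of view:

```r
library(plaquescope)

sp <- slide_spec(seed = 7)                    # 2560x2560 px, 0.5 um/px
hm <- generate_heatmap(sp, "cored")           # heatmap + ground truth
gt <- hm$ground_truth

wt <- compute_score(hm$heatmap, "cored", region = gt$tissue_mask,
                    slide_id = "demo")
gm <- compute_score(hm$heatmap, "cored", region = gt$gm_mask,
                    slide_id = "demo", region_label = "gray_matter")
rbind(wt, gm)
#>   slide_id class       region blob_count region_area_px    cnn_score
#> 1     demo cored whole_tissue          5          13381 0.0003736642
#> 2     demo cored  gray_matter          5           8029 0.0006227426
percent_change(gm, wt)
#> [1] 66.66  # restricting to gray matter raises the density score ~67%

fov <- compute_fov_scores(hm$heatmap, "cored", tissue_mask = gt$tissue_mask,
                          config = fov_config(window_size_px = 16, window_stride_px = 2))
head(select_top_n_nonoverlapping(fov, 3))     # densest non-overlapping fields
```

The five planted deposits are recovered exactly (`blob_count` equals
the generator's ground-truth count), the whole-tissue score is
5 / 13381 ≈ 3.7·10⁻⁴ blobs per heatmap pixel, and because deposits
concentrate in gray matter the gray-matter score is higher.

Training and applying the classifier:

```r
tiles <- generate_tile_set(2000, seed = 42)   # labeled 256x256 tiles
model <- train_cnn(build_cnn(seed = 1), tiles, epochs = 2, seed = 7)
model$history$val                              # per-class validation AUROC
slide <- generate_slide_image(slide_spec(width_px = 4096, height_px = 4096, seed = 11))
hm3 <- sliding_window_heatmap(model, slide$image,
                              tissue_mask = slide$ground_truth$tissue_mask,
                              stride = 16)     # 241 x 241 x 3
```

An end-to-end run over a synthetic cohort (scores, gray-matter
re-scores, FOV tables, statistics report, provenance manifest):

```r
res <- run_pipeline(cohort = cohort_spec(n_slides = 12), out_dir = "run1", seed = 5)
res$stats$cored$spearman
```

A thin command-line wrapper is installed at
`system.file("cli/plaquescope.R", package = "plaquescope")` with
`run`, `synth`, `score`, and `fov` subcommands.

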