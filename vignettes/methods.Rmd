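---
title: "Quantifying amyloid pathology in whole-slide images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid pathology in whole-slide images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neuropathological assessment of Alzheimer's disease relies on
semi-quantitative ratings of amyloid-beta (A&beta;) deposit density —
CERAD-style four-level scales (*none*, *sparse*, *moderate*,
*frequent*) assigned by a pathologist inspecting stained tissue.
`plaquescope` implements a quantitative alternative: a convolutional
classifier slides across a whole-slide image (WSI) of
4G8-immunostained cortex (DAB brown chromogen on a hematoxylin
counterstain), producing a per-class *confidence heatmap* for three
A&beta; morphologies — cored plaques, diffuse plaques, and cerebral
amyloid angiopathy (CAA). Each heatmap is reduced to a scalar **CNN
score**: the number of detected deposit blobs divided by the pixel
area of the scored region. The package covers the full chain —
color normalization, tissue segmentation, classifier training and
sliding-window inference, heatmap-to-score conversion with optional
gray-matter restriction, CERAD-style field-of-view (FOV) scoring, and
the cohort statistics that compare CNN scores with ordinal ratings —
together with a synthetic-slide generator that makes every stage
testable against exact ground truth.

## The pipeline stage by stage

### Color normalization and tissue segmentation

Staining intensity varies between labs and batches, so every slide is
matched to one reference via Reinhard color transfer: the image is
mapped to the Ruderman l&alpha;&beta; space (RGB &rarr; LMS cone
responses &rarr; log10 &rarr; a decorrelating rotation), each channel
is shifted and scaled to the reference mean and standard deviation,
and the result is mapped back to RGB. Two numerical choices matter:

* The forward RGB&rarr;LMS matrix is the published one; the inverse is
  computed as its exact matrix inverse rather than the independently
  rounded published inverse, so a round trip is lossless to machine
  precision.
* Pixels are clamped to `1e-6` before the log (black has no
  logarithm), and outputs are clipped to the RGB gamut. Normalizing
  twice against the same reference is idempotent up to one
  quantization step *provided the reference is gamut-compatible*;
  a wildly mismatched reference clips heavily and breaks this, which
  is why `default_reference_stats()` ships values typical of a
  well-stained slide rather than arbitrary round numbers.

Foreground tissue is segmented by thresholding in CIE LCH: a pixel is
tissue when lightness, chroma, and hue all fall inside configurable
closed bounds (defaults `L <= 94`, `chroma >= 4`, any hue). The bounds
are per-slide configurable because real cohorts need minimal
per-image tuning; on synthetic slides the defaults recover the true
tissue mask on more than 99% of pixels.

### The classifier

The model is deliberately small: six 3&times;3 convolution blocks
(zero padding, ReLU, 2&times;2 max pooling) that reduce a
256&times;256&times;3 window to 4&times;4 spatial resolution, followed
by dense layers of 512 and 100 units and **three independent sigmoid
outputs** — multilabel, because one tile can contain several
pathologies at once. Channel widths default to
8-16-16-32-32-64; widths, like the learning rate (2e-3), batch size
(16), and Adam moments, are configuration, not architecture. Inputs
are centered (x &minus; 0.5). The numerics (im2col GEMM convolutions,
single-precision arithmetic, per-sample backpropagation with
mini-batch Adam) live in compiled code; weights are initialized
He-normal from R's RNG, and all shuffles come from R, so a fixed seed
reproduces a run exactly on one machine. Across machines the
determinism contract is metric-level (same AUROC regime), as is usual
for floating-point training.

Inference slides the window at a fixed stride (default 16 WSI pixels),
writing the three probabilities to heatmap pixel `(i, j)` for the
window whose top-left is at `((i-1)*stride+1, (j-1)*stride+1)`; a
heatmap is therefore `floor((H-256)/stride)+1` pixels high. Windows
with less than 50% tissue coverage (configurable) are skipped and left
at zero — background dominates most slides and carries no signal.

### From heatmap to CNN score

Scoring a heatmap channel proceeds: *region mask &rarr; threshold
&rarr; morphological cleanup &rarr; blob labeling &rarr; count / area*.
The region mask (whole tissue, or its gray-matter subset) is applied
**before** thresholding, so a deposit straddling the region boundary is
truncated — possibly split — rather than kept or dropped whole; this
ordering is part of the method's definition and is tested. Defaults:
per-class probability threshold 0.9 (real deployments calibrate per
class — only the existence of class-specific thresholds is structural),
one opening then one closing with a 3&times;3 cross, 8-connectivity.
The score's units are blobs per heatmap pixel of region area; both
numerator and denominator live at heatmap resolution so the ratio is
internally consistent (whether the original analysis divided by WSI- or
heatmap-resolution area is not documented; one convention is fixed
here).

Gray-matter restriction reuses the same machinery with the mask
swapped, and `percent_change()` reports
`100 * (gm - wt) / wt` per slide and class, undefined (NA) when the
whole-tissue score is zero.

### Field-of-view scoring

CERAD practice scores the densest microscope field, so the package
also scores fixed-area windows: 251 heatmap pixels square, which at 16
WSI px per heatmap px and 0.5 &micro;m per WSI px is
`(251 * 16 * 0.5 um)^2 = 4.03 mm^2` — the area of a 10&times;
objective field. Three design choices the original description leaves
open are fixed as:

* blobs are detected once globally and assigned to windows by
  **centroid membership** with half-open window extents, so a
  non-overlapping tiling partitions the blob count exactly and
  overlapping windows never double-count within one window;
* the score denominator is the tissue area inside the window,
  consistent with the whole-tissue score;
* windows not fully inside the heatmap are skipped (constant physical
  area), and the FOV stride is interpreted in heatmap pixels.

Top-n selection is greedy by descending score with row-major
tie-breaking, discarding candidates that overlap a selected window —
optimal for n = 1 and property-tested against exhaustive search for
n = 2.

### Cohort statistics

All comparisons use standard tools: classical one-way ANOVA
(equal-variance F; Welch behind a flag) with Tukey HSD adjusted
p-values for every pair and adjacency flags for ordered groupings;
pooled-variance two-sided t-tests; tie-corrected Kruskal–Wallis for
outlier-heavy classes; and tie-corrected (midrank) Spearman rank
correlation against ordinal levels encoded 0..3. Only Tukey's
adjustment is applied within a family, and no cross-family correction
is made, matching the reporting style the pipeline emulates.
Diagnosis groupings implement the cohort's inclusion rules:
probable/possible AD count as AD; amygdala-predominant Lewy body
disease does not count toward the LBD group (but stays in "all AD");
clinically-normal cases with AD pathology are excluded by default
(toggleable); NIA-Reagan levels *no* and *low* are pooled.

## The synthetic-data generator

Every stage is validated on synthetic slides with exact ground truth.
What the generator emulates — and what it does not — bounds what
passing tests show about real data.

**Geometry.** Tissue is an ellipse inscribed in the slide (semi-axes
45% of each dimension); gray matter is the concentric ellipse scaled
by `sqrt(gm_fraction)`, so its area fraction of tissue is exactly
`gm_fraction` (default 0.6). Real cortex is a folded ribbon, not an
ellipse; only the area accounting and containment relations matter for
the tests.

**Deposits.** Three morphologies are planted at heatmap scale:
cored = discs (radius 2 px), diffuse = irregular multi-disc patches
(bounding radius 6), CAA = annuli (outer radius 5). These are
separability stand-ins, not claims about plaque geometry (no
quantitative morphology is documented for the real classes). Placement
guarantees a minimum gap between same-class blobs (default 8 heatmap
px, > 2&times; the cleaning element, so closing cannot merge planted
blobs) and a safety margin from the gray-matter boundary, so every blob
is wholly inside or wholly outside gray matter — the basis of the
partition-conservation test. A `white_matter_leak` fraction of deposits
is placed in white matter. Expected counts are `round(density x
gray-matter area)`; densities are per mm² of gray matter. Placement is
rejection sampling; requesting densities near the random-sequential-
adsorption jamming limit of the region fails with an explicit error,
and the default cohort densities (cored up to 30 /mm², diffuse 11,
CAA 9 at the *frequent* level) were chosen to stay well below that
limit for the default 2560-px slide (diffuse blobs are large, so their
feasible range is lower).

**Rendering.** Slide images use a hematoxylin-toned tissue color with
per-class DAB-brown tones and Gaussian pixel noise (sd 0.02). The
palette makes the three classes clearly color-separable — by design:
the classifier tests require separable tiles, and the generator's
contract is separability, not photorealism. Large pale morphologies
are painted before small dense ones so no planted deposit is occluded.
Fading, tears, artifacts, and staining batch effects are **not**
modeled; a model that aces these tiles has demonstrated the training
and inference machinery, not robustness to real histology.

**Heatmaps.** For scoring-stage tests, confidence heatmaps are planted
directly at heatmap resolution (deposit pixels 0.95, tissue background
uniform sub-threshold noise on [0, 0.3], zero outside tissue),
bypassing the CNN — this decouples stage testing from training.

**Cohorts.** Each slide receives one ordinal level (balanced across
the cohort) and planted densities `level density + N(0, noise_sd)`
truncated at zero — the simplest monotone-plus-noise structure. With
`noise_sd = 0` the expected score is exactly monotone in level.

## Scaled-down study conditions

The tests and the acceptance script run everything at desk scale on
one CPU. Problem sizes used: unit tests exercise the classifier at
64-px input; the full-scale loop trains the 256-px architecture for 2
epochs on 2,000 synthetic tiles (80/20 train/validation split) and
maps a 4096&times;4096 slide at stride 16 into a 241&times;241
heatmap; the cohort analysis uses 40 slides of 2560&times;2560 px
(145&times;145 heatmaps) over 200 seeds in the test suite and 25 seeds
in the acceptance script. The scaled-down FOV window is 16 heatmap px
(stride 2), chosen to preserve the *relative* window-to-tissue scale
of the full-size 251-px window on a real WSI.

One scaled-down behavior deserves a note: the median correlation
between mean-top-n FOV scores and ordinal level rises with n
(&approx;0.85 at n = 1 to &approx;0.92 at n = 5–7) and approaches but
never reaches the whole-tissue correlation (&approx;0.98) — then
*saturates and slightly declines* for larger n, because sparse
desk-scale slides simply run out of disjoint hotspot windows (their
mean-top-n is pinned while dense slides keep averaging in weaker
windows). The same decline appears for CAA in full-scale published
analyses; it is a property of small cohorts and bounded pathology, not
of the scoring method.

## Known limitations

* The conv channel widths, kernel sizes and activation of the original
  full-scale model are not documented; the defaults here are declared
  configuration, and no attempt is made to reproduce published weights
  or institutional-cohort statistics.
* Per-class probability thresholds default to 0.9 for all classes;
  real data require per-class calibration.
* The generator's ellipse geometry and shape stand-ins mean
  morphology-sensitive extensions (size distributions, shape
  classification) cannot be validated against it.
* Training determinism is exact only on a fixed machine/BLAS; across
  platforms the contract is the achieved metric, not the bit pattern.
* Region annotations are accepted as JSON polygons or PNG masks; the
  annotation-server SVG dialect of production deployments is out of
  scope, and polygons are rasterized by window-center sampling (exact
  for pixel-center semantics, &plusmn;1 boundary pixel otherwise).
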