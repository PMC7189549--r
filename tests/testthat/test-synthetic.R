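# Synthetic slide / heatmap / cohort generator: ground-truth consistency,
# determinism, and validation behaviour.

small_spec <- function(...) {
  slide_spec(width_px = 1024L, height_px = 1024L, ...)
}

test_that("spec validation rejects out-of-range parameters", {
  expect_error(slide_spec(gm_fraction = 1.2), "\\[0, 1\\]")
  expect_error(slide_spec(white_matter_leak = -0.1), "\\[0, 1\\]")
  expect_error(slide_spec(class_densities = c(cored = -1, diffuse = 0,
                                              caa = 0)), "non-negative")
  expect_error(slide_spec(width_px = 100), "width_px")
  expect_error(cohort_spec(n_slides = 2), "at least")
  expect_error(cohort_spec(density_by_level = list(
    cored = c(3, 2, 1, 0), diffuse = 1:4, caa = 1:4)), "increasing")
  expect_error(cohort_spec(noise_sd = -1), "non-negative")
})

test_that("zero density yields an empty heatmap and count zero", {
  sp <- small_spec(class_densities = c(cored = 0, diffuse = 0, caa = 0),
                   seed = 3)
  hm <- generate_heatmap(sp, "cored")
  expect_equal(hm$ground_truth$count_total, 0)
  expect_equal(sum(hm$ground_truth$deposit_mask), 0)
  # sub-threshold tissue noise only: nothing at or above 0.9
  expect_true(all(hm$heatmap < 0.9))
  expect_true(all(hm$heatmap >= 0) && all(hm$heatmap <= 1))
})

test_that("planted deposits are recovered by an independent flood fill", {
  for (seed in c(2, 9, 31)) {
    sp <- small_spec(class_densities = c(cored = 25, diffuse = 10, caa = 8),
                     white_matter_leak = 0, seed = seed)
    for (cl in c("cored", "diffuse", "caa")) {
      hm <- generate_heatmap(sp, cl)
      ff <- flood_fill_components(hm$ground_truth$deposit_mask, 8)
      expect_equal(ff$count, hm$ground_truth$count_total,
                   info = paste(cl, seed))
      expect_equal(nrow(hm$ground_truth$centroids),
                   hm$ground_truth$count_total)
    }
  }
})

test_that("identical spec and seed give bit-identical output", {
  sp <- small_spec(seed = 11)
  a <- generate_heatmap(sp, "diffuse")
  b <- generate_heatmap(sp, "diffuse")
  expect_identical(a, b)
  ia <- generate_slide_image(slide_spec(width_px = 512L, height_px = 512L,
                                        seed = 4))
  ib <- generate_slide_image(slide_spec(width_px = 512L, height_px = 512L,
                                        seed = 4))
  expect_identical(ia, ib)
  # and the generator restores the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_heatmap(sp, "cored")); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("mask containment invariants hold", {
  sp <- slide_spec(width_px = 1792L, height_px = 1792L, gm_fraction = 0.5,
                   white_matter_leak = 0.3,
                   class_densities = c(cored = 30, diffuse = 5, caa = 5),
                   seed = 8)
  hm <- generate_heatmap(sp, "cored")
  gt <- hm$ground_truth
  expect_true(all(gt$tissue_mask[gt$gm_mask]))          # gm subset tissue
  expect_true(all(gt$tissue_mask[gt$deposit_mask]))     # deposits in tissue
  expect_lte(gt$count_gm, gt$count_total)
  # heatmap zero outside tissue
  expect_true(all(hm$heatmap[!gt$tissue_mask] == 0))
})

test_that("gm_fraction 1 with no leak puts every centroid in gray matter", {
  sp <- small_spec(gm_fraction = 1, white_matter_leak = 0,
                   class_densities = c(cored = 20, diffuse = 0, caa = 0),
                   seed = 6)
  hm <- generate_heatmap(sp, "cored")
  gt <- hm$ground_truth
  cent <- round(gt$centroids)
  expect_true(all(gt$gm_mask[cbind(cent[, 1], cent[, 2])]))
  # and leak with gm_fraction 1 is impossible
  sp2 <- small_spec(gm_fraction = 1, white_matter_leak = 0.5,
                    class_densities = c(cored = 20, diffuse = 0, caa = 0))
  expect_error(generate_heatmap(sp2, "cored"), "gm_fraction")
})

test_that("infeasible densities raise a placement error", {
  sp <- small_spec(class_densities = c(cored = 3000, diffuse = 0, caa = 0),
                   seed = 1)
  expect_error(generate_heatmap(sp, "cored"), "minimum")
})

test_that("slide image aligns with its ground truth and segments cleanly", {
  sp <- small_spec(seed = 5)
  si <- generate_slide_image(sp)
  gt <- si$ground_truth
  expect_equal(dim(si$image), c(1024, 1024, 3))
  expect_true(all(si$image >= 0 & si$image <= 1))
  expect_true(all(gt$tissue_mask[gt$gm_mask]))
  for (cl in names(gt$deposit_masks)) {
    ff <- flood_fill_components(gt$deposit_masks[[cl]], 8)
    expect_equal(ff$count, unname(gt$counts[cl]))
  }
  # LCH segmentation of the rendered image recovers the tissue mask
  seg <- segment_tissue_lch(si$image)
  expect_gte(mean(seg == gt$tissue_mask), 0.99)
})

test_that("tile labeling follows the overlap threshold", {
  # blank image: all labels negative
  blank <- list(image = array(0.8, c(128, 128, 3)),
                ground_truth = list(deposit_masks = list(
                  cored = matrix(FALSE, 128, 128),
                  diffuse = matrix(FALSE, 128, 128),
                  caa = matrix(FALSE, 128, 128))))
  lt <- generate_labeled_tiles(blank$image, blank$ground_truth,
                               tile_size = 64L)
  expect_equal(sum(lt$labels), 0)

  # one deposit wholly inside one tile -> exactly that tile positive
  dm <- matrix(FALSE, 128, 128); dm[20:30, 20:30] <- TRUE
  gt1 <- list(deposit_masks = list(cored = dm,
                                   diffuse = matrix(FALSE, 128, 128),
                                   caa = matrix(FALSE, 128, 128)))
  lt1 <- generate_labeled_tiles(blank$image, gt1, tile_size = 64L)
  expect_equal(lt1$labels[, "cored"], c(1L, 0L, 0L, 0L))

  # deposit straddling two tiles with threshold 1 -> both positive;
  # a high threshold keeps only the tile holding enough pixels
  dm2 <- matrix(FALSE, 128, 128); dm2[60:70, 20:30] <- TRUE  # rows 60..70
  gt2 <- list(deposit_masks = list(cored = dm2,
                                   diffuse = matrix(FALSE, 128, 128),
                                   caa = matrix(FALSE, 128, 128)))
  lt2 <- generate_labeled_tiles(blank$image, gt2, tile_size = 64L,
                                overlap_threshold = 1L)
  expect_equal(lt2$labels[, "cored"], c(1L, 0L, 1L, 0L))
  lt3 <- generate_labeled_tiles(blank$image, gt2, tile_size = 64L,
                                overlap_threshold = 60L)
  # 5 rows x 11 cols = 55 px in the upper tile, 6 x 11 = 66 in the lower
  expect_equal(lt3$labels[, "cored"], c(0L, 0L, 1L, 0L))

  expect_error(generate_labeled_tiles(blank$image, gt2, tile_size = 256L),
               "larger")
})

test_that("cohort generation is monotone in the ordinal level", {
  cs <- cohort_spec(n_slides = 12, noise_sd = 0, seed = 21,
                    slide_template = small_spec())
  gen <- generate_cohort(cs)
  rec <- gen$records
  # noise 0: all slides at one level share the planted density
  for (lv in levels(rec$level_cored)) {
    d <- rec$density_cored[rec$level_cored == lv]
    expect_true(length(unique(d)) == 1)
  }
  # perfect rank correlation between level index and density, ties aside
  expect_equal(suppressWarnings(
    cor(as.integer(rec$level_cored), rec$density_cored,
        method = "spearman")), 1)
  # densities carried onto the slide specs
  expect_equal(gen$slide_specs[[3]]$class_densities[["cored"]],
               rec$density_cored[3])
  # balanced level assignment
  expect_true(all(table(rec$level_cored) == 3))
})

test_that("tile sets are reproducible and carry coherent labels", {
  a <- generate_tile_set(6, tile_size = 64L, seed = 5)
  b <- generate_tile_set(6, tile_size = 64L, seed = 5)
  expect_identical(a, b)
  expect_equal(dim(a$labels), c(6L, 3L))
  # positive tiles contain dark (deposit) pixels, negatives only tissue
  dark <- vapply(a$tiles, function(r) min(as.integer(r)), 0)
  has_any <- rowSums(a$labels) > 0
  if (any(has_any) && any(!has_any))
    expect_lt(max(dark[has_any]), min(dark[!has_any]))
})
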