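# Heatmap thresholding, morphological cleanup, blob labeling, and the
# density (CNN) score.

test_that("thresholding matches elementwise comparison", {
  hm <- matrix(c(0.1, 0.5, 0.9,
                 0.45, 0.5, 0.55,
                 0.0, 1.0, 0.49), 3, 3, byrow = TRUE)
  expect_true(all(threshold_heatmap(hm, 0)))
  expect_equal(sum(threshold_heatmap(matrix(0.9, 2, 2), 1)), 0)
  expect_equal(threshold_heatmap(hm, 0.5), hm >= 0.5)
  expect_error(threshold_heatmap(hm, 1.5), "\\[0, 1\\]")
})

test_that("morphological cleanup removes speckle and keeps solid shapes", {
  x <- matrix(FALSE, 9, 9); x[5, 5] <- TRUE
  expect_equal(sum(clean_binary(x)), 0)              # isolated pixel opened away
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  # a box element preserves the solid square exactly; the cross element
  # shaves the four corners (erosion to 3x3, dilation to the 5x5 minus
  # corners) but keeps it one blob
  expect_equal(clean_binary(sq, morphology_params(element = "box")), sq)
  crossed <- clean_binary(sq)
  expect_equal(sum(sq) - sum(crossed), 4)
  expect_equal(label_blobs(crossed)$count, 1)
  p0 <- morphology_params(opening = 0L, closing = 0L)
  rnd <- matrix(runif(81) > 0.5, 9, 9)
  expect_equal(clean_binary(rnd, p0), rnd)           # zero iterations: identity
  # closing bridges a 1-px gap that opening alone would leave
  gap <- matrix(FALSE, 9, 9); gap[4:6, 3:4] <- TRUE; gap[4:6, 6:7] <- TRUE
  pc <- morphology_params(opening = 0L, closing = 1L)
  bridged <- clean_binary(gap, pc)
  expect_true(bridged[5, 5])                         # center of the gap filled
  expect_equal(label_blobs(bridged)$count, 1)        # halves now connected
  expect_equal(label_blobs(gap)$count, 2)
  expect_error(morphology_params(connectivity = 6), "4 or 8")
})

test_that("blob labeling matches connectivity semantics", {
  m <- matrix(0, 4, 4)
  expect_equal(label_blobs(m)$count, 0)
  diagm <- matrix(0, 3, 3); diagm[1, 1] <- 1; diagm[2, 2] <- 1
  expect_equal(label_blobs(diagm, 8)$count, 1)
  expect_equal(label_blobs(diagm, 4)$count, 2)
  five <- matrix(0, 20, 20)
  for (o in list(c(1, 1), c(1, 10), c(10, 1), c(10, 10), c(17, 17)))
    five[o[1] + 0:2, o[2] + 0:2] <- 1
  lb <- label_blobs(five, 8)
  expect_equal(lb$count, 5)
  expect_equal(sort(lb$sizes), rep(9L, 5))
  # centroid of a 3x3 square at rows 1:3, cols 1:3 is (2, 2)
  expect_equal(lb$centroids[1, ], c(row = 2, col = 2))
})

test_that("blob labeling equals flood fill on random rasters", {
  set.seed(42)
  for (i in 1:120) {
    H <- sample(3:40, 1); W <- sample(3:40, 1)
    dens <- runif(1, 0.1, 0.7)
    m <- matrix(runif(H * W) < dens, H, W)
    for (conn in c(4L, 8L)) {
      got <- label_blobs(m, conn)
      ff <- flood_fill_components(m, conn)
      expect_identical(got$count, ff$count)
      expect_identical(sort(got$sizes), ff$sizes)
    }
  }
})

test_that("scores recover planted deposits and scale with region area", {
  hm <- plant_discs(80, 80, rbind(c(10, 10), c(10, 40), c(40, 10),
                                  c(40, 40), c(70, 70)))
  region <- matrix(TRUE, 80, 80)
  sc <- compute_score(hm, "cored", region = region)
  expect_equal(sc$blob_count, 5)
  expect_equal(sc$cnn_score, 5 / 6400)
  expect_equal(sc$region, "whole_tissue")
  # zero heatmap
  sc0 <- compute_score(matrix(0, 30, 30), "caa",
                       region = matrix(TRUE, 30, 30))
  expect_equal(sc0$blob_count, 0)
  expect_equal(sc0$cnn_score, 0)
  # restricting the region to 3 of 5 deposits (area 40 x 50)
  gm <- matrix(FALSE, 80, 80); gm[1:50, 1:50] <- TRUE
  scg <- compute_score(hm, "cored", region = gm,
                       region_label = "gray_matter")
  expect_equal(scg$blob_count, 4)
  expect_equal(scg$cnn_score, 4 / 2500)
  # empty region is an error
  expect_error(compute_score(hm, "cored", region = matrix(FALSE, 80, 80)),
               "empty region")
  # doubling the region area without new blobs halves the score
  big <- matrix(TRUE, 80, 160)
  hm_big <- cbind(hm, matrix(0, 80, 80))
  sc2 <- compute_score(hm_big, "cored", region = big)
  expect_equal(sc2$cnn_score, sc$cnn_score / 2)
})

test_that("masking happens before blob detection", {
  # one blob straddling the region boundary is truncated, not dropped
  hm <- plant_discs(40, 40, rbind(c(20, 20)), radius = 4)
  left <- matrix(FALSE, 40, 40); left[, 1:20] <- TRUE
  sc <- compute_score(hm, "cored", region = left)
  expect_equal(sc$blob_count, 1)  # half-disc survives cleaning
  # region area is the mask area, not the tissue area
  expect_equal(sc$region_area_px, sum(left))
})

test_that("raising the threshold never increases coverage; score rises with density", {
  sp <- slide_spec(width_px = 1024L, height_px = 1024L, seed = 13,
                   class_densities = c(cored = 20, diffuse = 0, caa = 0))
  hm <- generate_heatmap(sp, "cored")$heatmap
  cov <- sapply(c(0.2, 0.5, 0.8, 0.95), function(t)
    sum(threshold_heatmap(hm, t)))
  expect_true(all(diff(cov) <= 0))
  score_at <- function(d, seed) {
    s <- slide_spec(width_px = 1024L, height_px = 1024L, seed = seed,
                    class_densities = c(cored = d, diffuse = 0, caa = 0))
    g <- generate_heatmap(s, "cored")
    compute_score(g$heatmap, "cored",
                  region = g$ground_truth$tissue_mask)$cnn_score
  }
  lo <- mean(sapply(1:5, function(s) score_at(8, s)))
  hi <- mean(sapply(1:5, function(s) score_at(40, s)))
  expect_gt(hi, lo)
})

test_that("gray-matter partition is additive and percent change is exact", {
  sp <- slide_spec(width_px = 1792L, height_px = 1792L, gm_fraction = 0.55,
                   white_matter_leak = 0.2, seed = 17,
                   class_densities = c(cored = 30, diffuse = 10, caa = 6))
  hm <- generate_heatmap(sp, "cored")
  gt <- hm$ground_truth
  wt <- compute_score(hm$heatmap, "cored", region = gt$tissue_mask,
                      slide_id = "s")
  gm <- compute_score(hm$heatmap, "cored", region = gt$gm_mask,
                      slide_id = "s", region_label = "gray_matter")
  compl <- compute_score(hm$heatmap, "cored",
                         region = gt$tissue_mask & !gt$gm_mask,
                         slide_id = "s", region_label = "white_matter")
  expect_equal(wt$blob_count, gm$blob_count + compl$blob_count)
  expect_equal(gm$blob_count, gt$count_gm)
  expect_lte(gm$region_area_px, wt$region_area_px)
  # percent change arithmetic
  g <- data.frame(slide_id = "s", class = "cored", cnn_score = 1.23e-3)
  w <- data.frame(slide_id = "s", class = "cored", cnn_score = 1.00e-3)
  expect_equal(percent_change(g, w), 23)
  g2 <- transform(g, cnn_score = 0.771e-3)
  expect_equal(percent_change(g2, w), -22.9)
  expect_equal(percent_change(w, w), 0)
  w0 <- transform(w, cnn_score = 0)
  expect_true(is.na(percent_change(g, w0)))
  expect_error(percent_change(transform(g, slide_id = "other"), w),
               "same slide")
})
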