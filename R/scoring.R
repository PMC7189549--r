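## Heatmap -> CNN score conversion: threshold, morphological cleanup,
## blob labeling, and density scoring with optional region restriction.

#' Morphology / detection parameters for heatmap scoring
#'
#' Per-class probability thresholds, the structuring element used for
#' the opening-then-closing cleanup, and the blob connectivity. The
#' defaults are the smallest standard choices (3x3 cross, one iteration
#' of each operation, 8-connectivity, threshold 0.9 per class); real
#' deployments calibrate the thresholds per pathology class.
#'
#' @param thresholds named numeric in `[0, 1]`, one per class.
#' @param element structuring element shape: `"cross"` (3x3 diamond) or
#'   `"box"`.
#' @param element_size odd element side length (default 3).
#' @param opening,closing iteration counts (erode^n dilate^n and
#'   dilate^n erode^n respectively); 0 disables the operation.
#' @param connectivity 4 or 8.
#' @return a `morphology_params` object.
#' @export
morphology_params <- function(thresholds = c(cored = 0.9, diffuse = 0.9,
                                             caa = 0.9),
                              element = c("cross", "box"),
                              element_size = 3L, opening = 1L, closing = 1L,
                              connectivity = 8L) {
  element <- match.arg(element)
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  if (opening < 0 || closing < 0) stop("iteration counts must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (element_size %% 2 != 1 || element_size < 1)
    stop("element_size must be odd and positive")
  structure(list(thresholds = thresholds, element = element,
                 element_size = as.integer(element_size),
                 opening = as.integer(opening), closing = as.integer(closing),
                 connectivity = as.integer(connectivity)),
            class = "morphology_params")
}

.brush <- function(params) {
  EBImage::makeBrush(params$element_size,
                     shape = if (params$element == "cross") "diamond"
                             else "box")
}

#' Threshold a heatmap channel into a binary raster
#'
#' Probabilities below the threshold are zeroed and treated as noise.
#'
#' @param heatmap numeric matrix of probabilities.
#' @param threshold scalar in `[0, 1]`; pixels with probability
#'   `>= threshold` are kept.
#' @return logical matrix.
#' @export
threshold_heatmap <- function(heatmap, threshold) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a scalar in [0, 1]")
  heatmap >= threshold
}

#' Morphologically clean a binary raster
#'
#' Opening (erosion then dilation, removing speckle smaller than the
#' structuring element) followed by closing (dilation then erosion,
#' filling small gaps), with the configured element and iteration
#' counts. Zero iterations of both is the identity.
#'
#' @param raster logical or 0/1 matrix.
#' @param params a [morphology_params()] object.
#' @return logical matrix.
#' @export
clean_binary <- function(raster, params = morphology_params()) {
  stopifnot(inherits(params, "morphology_params"))
  x <- matrix(as.numeric(raster), nrow(raster), ncol(raster))
  if (params$opening == 0 && params$closing == 0) return(x > 0.5)
  kern <- .brush(params)
  for (i in seq_len(params$opening)) x <- EBImage::erode(x, kern)
  for (i in seq_len(params$opening)) x <- EBImage::dilate(x, kern)
  for (i in seq_len(params$closing)) x <- EBImage::dilate(x, kern)
  for (i in seq_len(params$closing)) x <- EBImage::erode(x, kern)
  matrix(x > 0.5, nrow(raster), ncol(raster))
}

#' Label connected components (blobs) of a binary raster
#'
#' @param raster logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return list with `labels` (integer matrix, 0 = background), `count`,
#'   `centroids` (count x 2 matrix of mean row/col, 1-based), `sizes`.
#' @export
label_blobs <- function(raster, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  bin <- matrix(as.integer(as.logical(raster)), nrow(raster), ncol(raster))
  .cpp_label_components(bin, as.integer(connectivity))
}

#' Compute the CNN score of one heatmap channel within a region
#'
#' The region mask (whole tissue, or the gray-matter subset) is applied
#' to the heatmap *before* thresholding and blob detection, so deposits
#' outside the region are removed at the probability level; the score is
#' the number of detected blobs divided by the region area in heatmap
#' pixels.
#'
#' @param heatmap numeric probability matrix (one class channel).
#' @param class_id pathology class name (used for the threshold lookup
#'   and carried into the result).
#' @param params a [morphology_params()] object.
#' @param region logical matrix aligned to the heatmap (the scoring
#'   region); its `TRUE` count is the score denominator.
#' @param slide_id identifier carried into the result.
#' @param region_label `"whole_tissue"` or `"gray_matter"` (free text).
#' @return a one-row data.frame (class `score_result`): `slide_id`,
#'   `class`, `region`, `blob_count`, `region_area_px`, `cnn_score`.
#' @export
compute_score <- function(heatmap, class_id, params = morphology_params(),
                          region = NULL, slide_id = "slide",
                          region_label = "whole_tissue") {
  stopifnot(inherits(params, "morphology_params"))
  if (is.null(region)) region <- matrix(TRUE, nrow(heatmap), ncol(heatmap))
  if (!identical(dim(region), dim(heatmap)))
    stop("region mask must be aligned to the heatmap")
  area <- sum(region)
  if (area == 0) stop("empty region mask: score undefined")
  masked <- heatmap
  masked[!region] <- 0
  thr <- params$thresholds[[class_id]]
  if (is.null(thr) || is.na(thr))
    stop("no threshold configured for class ", class_id)
  bin <- threshold_heatmap(masked, thr)
  bin <- clean_binary(bin, params)
  lab <- label_blobs(bin, params$connectivity)
  res <- data.frame(slide_id = slide_id, class = class_id,
                    region = region_label, blob_count = lab$count,
                    region_area_px = area,
                    cnn_score = lab$count / area,
                    stringsAsFactors = FALSE)
  class(res) <- c("score_result", class(res))
  res
}

#' Percent change between gray-matter and whole-tissue scores
#'
#' `100 * (gm - wt) / wt`; positive when restricting to gray matter
#' increases the density score.
#'
#' @param gm,wt `score_result` rows (or any objects with a `cnn_score`
#'   column) for the same slide and class.
#' @return signed percent, or `NA` when the whole-tissue score is zero
#'   (undefined).
#' @export
percent_change <- function(gm, wt) {
  g <- gm$cnn_score; w <- wt$cnn_score
  if (!is.null(gm$slide_id) && !is.null(wt$slide_id) &&
      (!identical(gm$slide_id, wt$slide_id) ||
       !identical(gm$class, wt$class)))
    stop("percent_change requires the same slide and class")
  ifelse(w > 0, 100 * (g - w) / w, NA_real_)
}

#' Downsample a slide-resolution mask to the heatmap grid
#'
#' Nearest-neighbour sampling at the center of each sliding window, the
#' convention used to align region annotations with heatmap pixels.
#'
#' @param mask logical matrix at slide resolution.
#' @param spec a [slide_spec()] (supplies window and stride), or `NULL`
#'   to pass `window`/`stride` directly.
#' @param window,stride sliding-window geometry in slide pixels.
#' @return logical matrix at heatmap resolution.
#' @export
downsample_mask <- function(mask, spec = NULL, window = 256L, stride = 16L) {
  if (!is.null(spec)) { window <- spec$window; stride <- spec$stride }
  H <- nrow(mask); W <- ncol(mask)
  hh <- (H - window) %/% stride + 1L
  hw <- (W - window) %/% stride + 1L
  rows <- pmin(H, (seq_len(hh) - 1L) * stride + window %/% 2L)
  cols <- pmin(W, (seq_len(hw) - 1L) * stride + window %/% 2L)
  mask[rows, cols, drop = FALSE]
}
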