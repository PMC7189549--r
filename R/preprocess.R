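## Preprocessing: Reinhard color normalization in the Ruderman l-alpha-beta
## space, LCH tissue segmentation, and image tiling.

# RGB <-> LMS transforms of the Ruderman decorrelated color space.
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
# exact inverse (the published rounded inverse would break round trips)
.lms2rgb <- solve(.rgb2lms)
.lab_fwd <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab_inv <- t(matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)) %*%
  diag(c(sqrt(3) / 3, sqrt(6) / 6, sqrt(2) / 2))

.as_pixel_matrix <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3] == 3L)
  matrix(image, ncol = 3L)
}

#' Convert an RGB image to the Ruderman l-alpha-beta color space
#'
#' The decorrelated, log-compressed color space used by Reinhard color
#' transfer: RGB is mapped to LMS cone responses, log10-compressed, and
#' rotated into a lightness axis (l) and two opponent chromatic axes
#' (alpha: yellow-blue, beta: red-green).
#'
#' @param image numeric array `H x W x 3`, values in `[0, 1]`.
#' @return numeric array `H x W x 3` of l, alpha, beta channels.
#' @export
rgb_to_ruderman_lab <- function(image) {
  px <- .as_pixel_matrix(image)
  px <- pmin(pmax(px, 1e-6), 1)       # log of 0 undefined; black is clamped
  lms <- log10(px %*% t(.rgb2lms))
  out <- lms %*% t(.lab_fwd)
  array(out, dim = dim(image))
}

#' @rdname rgb_to_ruderman_lab
#' @param lab numeric array `H x W x 3` of l, alpha, beta values.
#' @export
ruderman_lab_to_rgb <- function(lab) {
  px <- matrix(lab, ncol = 3L)
  lms <- 10 ^ (px %*% t(.lab_inv))
  out <- lms %*% t(.lms2rgb)
  array(pmin(pmax(out, 0), 1), dim = dim(lab))
}

#' Channelwise statistics of an image in Ruderman l-alpha-beta space
#'
#' @param image numeric RGB array `H x W x 3` in `[0, 1]`.
#' @return an object of class `lab_stats`: list with `mean` and `sd`,
#'   each a length-3 numeric vector (l, alpha, beta).
#' @export
compute_lab_stats <- function(image) {
  lab <- matrix(rgb_to_ruderman_lab(image), ncol = 3L)
  s <- apply(lab, 2L, stats::sd)
  if (any(!is.finite(s)) || any(s <= 1e-12))
    stop("zero-variance channel: Reinhard normalization is undefined for ",
         "constant-color images")
  structure(list(mean = colMeans(lab), sd = s), class = "lab_stats")
}

#' @export
print.lab_stats <- function(x, ...) {
  cat("Ruderman l-alpha-beta statistics\n")
  m <- rbind(mean = x$mean, sd = x$sd)
  colnames(m) <- c("l", "alpha", "beta")
  print(round(m, 4))
  invisible(x)
}

.check_lab_stats <- function(x, what) {
  if (!inherits(x, "lab_stats")) stop(what, " must be a `lab_stats` object")
  if (any(!is.finite(c(x$mean, x$sd))) || any(x$sd <= 0))
    stop(what, " has non-finite or non-positive values")
  invisible(x)
}

#' Default reference color statistics
#'
#' Shipped reference statistics in Ruderman l-alpha-beta space describing
#' a reference-quality DAB / hematoxylin slide (pale background, moderate
#' chromatic spread); the values are the rounded statistics of a
#' reference-quality synthetic slide, so normalizing typical slides
#' against them involves negligible gamut clipping. Every slide in a
#' study should be normalized against the same reference; replace these
#' with statistics of a chosen reference slide via [compute_lab_stats()]
#' when one is available.
#'
#' @return a `lab_stats` object.
#' @export
default_reference_stats <- function() {
  structure(list(mean = c(-0.13, -0.02, 0.0), sd = c(0.11, 0.036, 0.004)),
            class = "lab_stats")
}

#' Reinhard color normalization
#'
#' Shifts and scales each Ruderman l-alpha-beta channel of `image` so its
#' statistics match `reference`, then maps back to RGB (clipped to
#' `[0, 1]`). Matching every slide of a cohort to one reference removes
#' staining-intensity variation before analysis.
#'
#' @param image numeric RGB array `H x W x 3` in `[0, 1]`.
#' @param reference `lab_stats` of the reference image
#'   (default [default_reference_stats()]).
#' @param source `lab_stats` of `image`; computed from `image` if `NULL`.
#' @return normalized RGB array, same dimensions as `image`.
#' @export
reinhard_normalize <- function(image, reference = default_reference_stats(),
                               source = NULL) {
  if (is.null(source)) source <- compute_lab_stats(image)
  .check_lab_stats(source, "source")
  .check_lab_stats(reference, "reference")
  lab <- matrix(rgb_to_ruderman_lab(image), ncol = 3L)
  for (k in 1:3)
    lab[, k] <- (lab[, k] - source$mean[k]) / source$sd[k] *
      reference$sd[k] + reference$mean[k]
  ruderman_lab_to_rgb(array(lab, dim = dim(image)))
}

#' Convert an RGB image to CIE LCH (lightness, chroma, hue)
#'
#' @param image numeric RGB array `H x W x 3` in `[0, 1]` (sRGB).
#' @return array `H x W x 3` with L in `[0, 100]`, chroma `>= 0`, hue in
#'   degrees `[0, 360)`.
#' @export
rgb_to_lch <- function(image) {
  px <- .as_pixel_matrix(image)
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  ch <- sqrt(lab[, 2]^2 + lab[, 3]^2)
  hue <- (atan2(lab[, 3], lab[, 2]) * 180 / pi) %% 360
  array(cbind(lab[, 1], ch, hue), dim = dim(image))
}

#' LCH tissue-segmentation thresholds
#'
#' A pixel is tissue when all three LCH channel values fall inside the
#' closed bounds. The defaults exclude the near-white, near-achromatic
#' slide background (high L, low chroma) and keep stained tissue; the
#' bounds are deliberately per-slide configurable since staining
#' variation usually requires minimal per-image tuning.
#'
#' @param lightness,chroma,hue length-2 numeric `c(lower, upper)` per
#'   channel (L in 0-100, chroma >= 0, hue in degrees 0-360).
#' @return an `lch_thresholds` object.
#' @export
lch_thresholds <- function(lightness = c(0, 94), chroma = c(4, 200),
                           hue = c(0, 360)) {
  th <- list(l = as.numeric(lightness), c = as.numeric(chroma),
             h = as.numeric(hue))
  for (nm in names(th)) {
    if (length(th[[nm]]) != 2L || any(!is.finite(th[[nm]])))
      stop("threshold `", nm, "` must be a finite c(lower, upper)")
    if (th[[nm]][1] > th[[nm]][2])
      stop("threshold `", nm, "` has lower > upper")
  }
  structure(th, class = "lch_thresholds")
}

#' Segment foreground tissue by LCH thresholding
#'
#' @param image numeric RGB array `H x W x 3` in `[0, 1]`.
#' @param thresholds an [lch_thresholds()] object.
#' @return logical `H x W` matrix (TRUE = tissue) with attribute
#'   `area_px`, the tissue pixel count.
#' @export
segment_tissue_lch <- function(image, thresholds = lch_thresholds()) {
  if (!inherits(thresholds, "lch_thresholds"))
    stop("`thresholds` must come from lch_thresholds()")
  lch <- rgb_to_lch(image)
  mask <- lch[, , 1] >= thresholds$l[1] & lch[, , 1] <= thresholds$l[2] &
          lch[, , 2] >= thresholds$c[1] & lch[, , 2] <= thresholds$c[2] &
          lch[, , 3] >= thresholds$h[1] & lch[, , 3] <= thresholds$h[2]
  attr(mask, "area_px") <- sum(mask)
  mask
}

#' Tile an image on a regular grid
#'
#' Pads the image right/bottom with white (background for both the
#' segmenter and the classifier) so the grid covers it completely, then
#' extracts `tile_size`-square tiles at the given stride in row-major
#' order.
#'
#' @param image numeric RGB array `H x W x 3`.
#' @param tile_size side length in pixels (default 256).
#' @param stride grid stride in pixels (default `tile_size`).
#' @param pad_value fill value for padded pixels (default 1, white).
#' @return list with `tiles` (list of arrays) and `coords` (data.frame
#'   with grid indices `row`, `col` and 1-based top-left slide pixels
#'   `y0`, `x0`).
#' @export
tile_image <- function(image, tile_size = 256L, stride = tile_size,
                       pad_value = 1) {
  stopifnot(tile_size >= 1L, stride >= 1L)
  d <- dim(image)
  pad_to <- function(n) {
    if (n <= tile_size) return(tile_size)
    tile_size + ceiling((n - tile_size) / stride) * stride
  }
  Hp <- pad_to(d[1]); Wp <- pad_to(d[2])
  if (Hp != d[1] || Wp != d[2]) {
    padded <- array(pad_value, dim = c(Hp, Wp, d[3]))
    padded[seq_len(d[1]), seq_len(d[2]), ] <- image
    image <- padded
  }
  nr <- (Hp - tile_size) %/% stride + 1L
  nc <- (Wp - tile_size) %/% stride + 1L
  coords <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, c("row", "col")]
  coords$y0 <- (coords$row - 1L) * stride + 1L
  coords$x0 <- (coords$col - 1L) * stride + 1L
  tiles <- lapply(seq_len(nrow(coords)), function(i) {
    y <- coords$y0[i]; x <- coords$x0[i]
    image[y:(y + tile_size - 1L), x:(x + tile_size - 1L), , drop = FALSE]
  })
  rownames(coords) <- NULL
  list(tiles = tiles, coords = coords)
}
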