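## CERAD-style field-of-view scoring: fixed-area windows over the
## heatmap, hotspot (top-n non-overlapping) selection, and convergence
## of top-n mean scores toward whole-tissue behaviour.

#' Field-of-view configuration
#'
#' The FOV emulates the ~4 mm^2 area of a 10x objective used in CERAD
#' practice. With the defaults -- a 251-heatmap-pixel window, 16 WSI
#' pixels per heatmap pixel (the sliding-window stride), and 0.5 um per
#' WSI pixel -- the physical window area is
#' `(251 * 16 * 0.5 um)^2 = 4.03 mm^2`.
#'
#' @param window_size_px FOV side length in heatmap pixels (default 251).
#' @param window_stride_px stride between FOV origins in heatmap pixels
#'   (default 16).
#' @param mpp microns per WSI pixel (default 0.5).
#' @param wsi_stride WSI pixels per heatmap pixel (default 16).
#' @return an `fov_config` object; its `area_mm2` element reports the
#'   physical window area.
#' @export
fov_config <- function(window_size_px = 251L, window_stride_px = 16L,
                       mpp = 0.5, wsi_stride = 16L) {
  stopifnot(window_size_px >= 1, window_stride_px >= 1, mpp > 0,
            wsi_stride >= 1)
  side_mm <- window_size_px * wsi_stride * mpp / 1000
  structure(list(window_size_px = as.integer(window_size_px),
                 window_stride_px = as.integer(window_stride_px),
                 mpp = mpp, wsi_stride = as.integer(wsi_stride),
                 area_mm2 = side_mm^2),
            class = "fov_config")
}

#' @export
print.fov_config <- function(x, ...) {
  cat(sprintf(
    "FOV: %d px window, stride %d (heatmap px); physical area %.2f mm^2\n",
    x$window_size_px, x$window_stride_px, x$area_mm2))
  invisible(x)
}

#' Score all fields of view of a heatmap
#'
#' Blobs are detected once globally (threshold, clean, label on the full
#' heatmap) and assigned to FOV windows by centroid membership, so a blob
#' is counted in every overlapping window but never twice within one;
#' over a non-overlapping tiling the window counts partition the total.
#' Only windows fully inside the heatmap are scored (constant physical
#' area), and only windows containing at least one blob centroid are
#' returned. The score denominator is the tissue area inside the window.
#'
#' @param heatmap numeric probability matrix (one class channel).
#' @param class_id pathology class name.
#' @param params a [morphology_params()] object.
#' @param tissue_mask logical matrix at heatmap resolution; `NULL` treats
#'   every pixel as tissue.
#' @param config an [fov_config()] object.
#' @return data.frame (class `fov_windows`): `row`, `col` (1-based
#'   top-left heatmap coordinates), `blob_count`, `tissue_area_px`,
#'   `fov_score`; window size kept as attribute `window_size_px`.
#' @export
compute_fov_scores <- function(heatmap, class_id,
                               params = morphology_params(),
                               tissue_mask = NULL, config = fov_config()) {
  stopifnot(inherits(config, "fov_config"))
  H <- nrow(heatmap); W <- ncol(heatmap)
  win <- config$window_size_px; step <- config$window_stride_px
  if (win > H || win > W) stop("FOV window larger than heatmap")
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, H, W)
  bin <- clean_binary(threshold_heatmap(heatmap,
                                        params$thresholds[[class_id]]),
                      params)
  lab <- label_blobs(bin, params$connectivity)
  empty <- data.frame(row = integer(0), col = integer(0),
                      blob_count = integer(0),
                      tissue_area_px = integer(0), fov_score = numeric(0))
  attr(empty, "window_size_px") <- win
  class(empty) <- c("fov_windows", class(empty))
  if (lab$count == 0) return(empty)
  origins_r <- seq(1L, H - win + 1L, by = step)
  origins_c <- seq(1L, W - win + 1L, by = step)
  counts <- matrix(0L, length(origins_r), length(origins_c))
  for (b in seq_len(lab$count)) {
    cr <- lab$centroids[b, 1]; cc <- lab$centroids[b, 2]
    # half-open window extent [o, o + win) so that fractional centroids
    # always belong to exactly one window of a non-overlapping tiling
    ri <- which(origins_r <= cr & cr < origins_r + win)
    ci <- which(origins_c <= cc & cc < origins_c + win)
    counts[ri, ci] <- counts[ri, ci] + 1L
  }
  keep <- which(counts > 0L, arr.ind = TRUE)
  # summed-area table for O(1) tissue area per window
  sat <- apply(apply(tissue_mask * 1, 2, cumsum), 1, cumsum)
  sat <- t(sat)
  rect_sum <- function(r0, c0, r1, c1) {
    s <- sat[r1, c1]
    if (r0 > 1) s <- s - sat[r0 - 1, c1]
    if (c0 > 1) s <- s - sat[r1, c0 - 1]
    if (r0 > 1 && c0 > 1) s <- s + sat[r0 - 1, c0 - 1]
    s
  }
  out <- data.frame(
    row = origins_r[keep[, 1]], col = origins_c[keep[, 2]],
    blob_count = counts[keep])
  out$tissue_area_px <- mapply(function(r, c)
    rect_sum(r, c, r + win - 1L, c + win - 1L), out$row, out$col)
  out$fov_score <- ifelse(out$tissue_area_px > 0,
                          out$blob_count / out$tissue_area_px, NA_real_)
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  attr(out, "window_size_px") <- win
  class(out) <- c("fov_windows", class(out))
  out
}

#' Select the top-n non-overlapping fields of view
#'
#' Greedy selection by descending FOV score; a candidate is discarded
#' when its pixel extent intersects any already-selected window. Ties are
#' broken by row-major origin order. May return fewer than `n` windows.
#'
#' @param windows an `fov_windows` data.frame.
#' @param n maximum number of windows (>= 1).
#' @param window_size_px window side; defaults to the attribute stored on
#'   `windows`.
#' @return the selected rows, highest score first.
#' @export
select_top_n_nonoverlapping <- function(windows, n,
                                        window_size_px =
                                          attr(windows, "window_size_px")) {
  stopifnot(n >= 1)
  if (nrow(windows) == 0) return(windows)
  if (is.null(window_size_px))
    stop("window_size_px not supplied and not stored on `windows`")
  ord <- order(-windows$fov_score, windows$row, windows$col)
  cand <- windows[ord, ]
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) >= n) break
    overlaps <- any(abs(cand$row[sel] - cand$row[i]) < window_size_px &
                    abs(cand$col[sel] - cand$col[i]) < window_size_px)
    if (!overlaps) sel <- c(sel, i)
  }
  out <- cand[sel, ]
  rownames(out) <- NULL
  attr(out, "window_size_px") <- window_size_px
  out
}

#' Mean score of the top-n non-overlapping fields of view
#'
#' @inheritParams select_top_n_nonoverlapping
#' @return arithmetic mean of `fov_score` over the selected windows;
#'   0 when no window qualifies.
#' @export
mean_top_n_score <- function(windows, n,
                             window_size_px =
                               attr(windows, "window_size_px")) {
  sel <- select_top_n_nonoverlapping(windows, n, window_size_px)
  if (nrow(sel) == 0) return(0)
  mean(sel$fov_score)
}

#' Convergence of top-n FOV scores toward whole-tissue correlation
#'
#' For each `n`, computes the Spearman rank correlation between the
#' per-slide mean top-n FOV score and the ordinal severity label, and
#' compares it with the whole-tissue score correlation -- the analysis
#' that asks how many densest fields a CERAD-style reading would need to
#' match whole-slide quantification. Also reports the correlation between
#' the single highest FOV score and the whole-tissue score.
#'
#' @param fov_by_slide named list of `fov_windows` data.frames, one per
#'   slide.
#' @param labels ordinal severity per slide (ordered factor or numeric),
#'   same order as `fov_by_slide`.
#' @param wt_scores per-slide whole-tissue CNN scores, same order.
#' @param n_values FOV counts to evaluate (default `c(1,3,...,15)`).
#' @return list of class `fov_convergence`: `table` (data.frame with
#'   `n_fov` -- including `"WT"` -- and `rho`), `top1_vs_wt` (Spearman
#'   between highest-FOV and whole-tissue scores), `mean_top_n` (matrix
#'   of per-slide mean top-n scores).
#' @export
convergence_table <- function(fov_by_slide, labels, wt_scores,
                              n_values = c(1L, 3L, 5L, 7L, 9L, 11L, 13L,
                                           15L)) {
  if (length(n_values) == 0) stop("n_values must be non-empty")
  n_slides <- length(fov_by_slide)
  if (n_slides < 3) stop("cohort of at least 3 slides required")
  stopifnot(length(labels) == n_slides, length(wt_scores) == n_slides)
  lab_rank <- if (is.numeric(labels)) labels else as.integer(labels)
  mt <- sapply(n_values, function(n)
    vapply(fov_by_slide, mean_top_n_score, 0, n = n))
  colnames(mt) <- n_values
  rho <- apply(mt, 2, function(s) spearman_ordinal(s, lab_rank))
  rho_wt <- spearman_ordinal(wt_scores, lab_rank)
  top1 <- mt[, 1]
  tab <- data.frame(n_fov = c(as.character(n_values), "WT"),
                    rho = c(rho, rho_wt), stringsAsFactors = FALSE)
  structure(list(table = tab,
                 top1_vs_wt = spearman_ordinal(top1, rank(wt_scores)),
                 mean_top_n = mt),
            class = "fov_convergence")
}

#' @export
print.fov_convergence <- function(x, ...) {
  cat("Spearman rho, mean top-n FOV score vs ordinal label:\n")
  print(transform(x$table, rho = round(rho, 3)), row.names = FALSE)
  cat(sprintf("Highest FOV vs whole-tissue score: rho = %.3f\n",
              x$top1_vs_wt))
  invisible(x)
}
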