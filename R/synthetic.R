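## Synthetic slide / heatmap / cohort generator with exact ground truth.
##
## Geometry: tissue is an ellipse inscribed in the slide (semi-axes 45% of
## each dimension); gray matter is a concentric ellipse whose axes are
## scaled by sqrt(gm_fraction), so its area is exactly gm_fraction of the
## tissue area. Deposits are planted with a guaranteed minimum gap between
## blobs of the same class and a safety margin from the gray-matter
## boundary, so that morphological cleaning can neither merge planted
## blobs nor make a blob straddle the boundary.

.classes <- c("cored", "diffuse", "caa")

# evaluate `code` under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default stain colors for the synthetic slide renderer
#'
#' Mean RGB and a global Gaussian noise sd emulating a hematoxylin
#' counterstained slide with DAB-brown amyloid deposits: near-white
#' background, pale blue-purple tissue, and per-class brown tones (cored
#' plaques dense and dark, diffuse deposits pale tan, CAA an intermediate
#' vessel-wall red-brown).
#'
#' @return named list of RGB triplets plus `noise_sd`.
#' @export
default_stain_params <- function() {
  list(background = c(0.96, 0.96, 0.96),
       tissue     = c(0.80, 0.76, 0.88),
       cored      = c(0.30, 0.18, 0.05),
       diffuse    = c(0.66, 0.52, 0.32),
       caa        = c(0.55, 0.26, 0.24),
       noise_sd   = 0.02)
}

# deposit morphologies at heatmap resolution; `bound` is the bounding
# radius used for separation and margin guarantees
.shape_params <- list(
  cored   = list(type = "disc",    r = 2,            bound = 2),
  diffuse = list(type = "patch",   r = 3,            bound = 6),
  caa     = list(type = "annulus", r_out = 5, r_in = 2, bound = 5)
)

#' Specification of one synthetic slide
#'
#' @param width_px,height_px slide dimensions in pixels.
#' @param mpp microns per pixel at scan magnification (default 0.5,
#'   i.e. 20x).
#' @param class_densities named vector, expected deposits per mm^2 of
#'   gray matter for `cored`, `diffuse`, `caa`.
#' @param gm_fraction fraction of tissue area that is gray matter,
#'   in `[0, 1]`.
#' @param white_matter_leak fraction of deposits placed outside gray
#'   matter (in white matter), in `[0, 1]`.
#' @param stain_params see [default_stain_params()].
#' @param window,stride classifier window and sliding-window stride in
#'   slide pixels; they fix the heatmap grid geometry.
#' @param min_gap_px minimum gap in heatmap pixels between planted blobs
#'   of one class (default 8, i.e. more than twice the 3x3 cleaning
#'   element, so opening/closing cannot merge blobs).
#' @param boundary_margin_px extra clearance in heatmap pixels between a
#'   blob edge and the gray-matter / tissue boundary (default 2).
#' @param seed integer; identical spec + seed gives bit-identical output.
#' @return a `slide_spec` object.
#' @export
slide_spec <- function(width_px = 2560L, height_px = 2560L, mpp = 0.5,
                       class_densities = c(cored = 8, diffuse = 5, caa = 3),
                       gm_fraction = 0.6, white_matter_leak = 0.05,
                       stain_params = default_stain_params(),
                       window = 256L, stride = 16L,
                       min_gap_px = 8L, boundary_margin_px = 2L,
                       seed = 1L) {
  stopifnot(width_px >= window, height_px >= window, mpp > 0,
            stride >= 1, min_gap_px >= 0, boundary_margin_px >= 0)
  if (any(is.na(class_densities)) || any(class_densities < 0))
    stop("class densities must be non-negative")
  if (is.null(names(class_densities)))
    names(class_densities) <- .classes[seq_along(class_densities)]
  if (!all(.classes %in% names(class_densities)))
    stop("class_densities must name ", paste(.classes, collapse = ", "))
  if (gm_fraction < 0 || gm_fraction > 1 ||
      white_matter_leak < 0 || white_matter_leak > 1)
    stop("gm_fraction and white_matter_leak must lie in [0, 1]")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), mpp = mpp,
                 class_densities = class_densities[.classes],
                 gm_fraction = gm_fraction,
                 white_matter_leak = white_matter_leak,
                 stain_params = stain_params,
                 window = as.integer(window), stride = as.integer(stride),
                 min_gap_px = min_gap_px,
                 boundary_margin_px = boundary_margin_px,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

#' @export
print.slide_spec <- function(x, ...) {
  cat(sprintf("Synthetic slide %d x %d px (%.2f um/px), seed %d\n",
              x$width_px, x$height_px, x$mpp, x$seed))
  cat(sprintf("  densities /mm^2 GM: cored %.2f, diffuse %.2f, caa %.2f\n",
              x$class_densities["cored"], x$class_densities["diffuse"],
              x$class_densities["caa"]))
  cat(sprintf("  gm_fraction %.2f, white_matter_leak %.2f\n",
              x$gm_fraction, x$white_matter_leak))
  invisible(x)
}

#' Heatmap grid dimensions implied by a slide spec
#'
#' The sliding window places its top-left corner at multiples of the
#' stride, so the heatmap has `floor((H - window) / stride) + 1` rows.
#'
#' @param spec a [slide_spec()].
#' @return integer c(rows, cols).
#' @export
heatmap_dim <- function(spec) {
  c((spec$height_px - spec$window) %/% spec$stride + 1L,
    (spec$width_px - spec$window) %/% spec$stride + 1L)
}

# ellipse membership on a raster grid; shrink > 0 contracts the ellipse
.ellipse_mask <- function(H, W, ay, ax, shrink = 0) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ay <- ay - shrink; ax <- ax - shrink
  if (ay <= 0 || ax <= 0) return(matrix(FALSE, H, W))
  ry <- ((seq_len(H) - cy) / ay)^2
  rx <- ((seq_len(W) - cx) / ax)^2
  outer(ry, rx, `+`) <= 1
}

.ellipse_test <- function(r, c, H, W, ay, ax, shrink = 0) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ay <- ay - shrink; ax <- ax - shrink
  if (ay <= 0 || ax <= 0) return(rep(FALSE, length(r)))
  ((r - cy) / ay)^2 + ((c - cx) / ax)^2 <= 1
}

# sequential rejection sampling of n centers with pairwise min distance
.place_points <- function(n, H, W, accept_fn, min_dist,
                          max_tries = 5000L * max(n, 1L)) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pr <- numeric(n); pc <- numeric(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    if (tries >= max_tries)
      stop("could not place ", n, " deposits at the configured minimum ",
           "separation: requested density too high for the region")
    r <- runif(1, 1, H); c <- runif(1, 1, W)
    tries <- tries + 1L
    if (!accept_fn(r, c)) next
    if (placed > 0L &&
        min((pr[seq_len(placed)] - r)^2 + (pc[seq_len(placed)] - c)^2) <
          min_dist^2) next
    placed <- placed + 1L
    pr[placed] <- r; pc[placed] <- c
  }
  cbind(row = pr, col = pc)
}

# paint one deposit shape into a logical raster, returning the raster
.paint_shape <- function(mask, r0, c0, shape) {
  H <- nrow(mask); W <- ncol(mask)
  paint_disc <- function(m, r0, c0, rad) {
    rs <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
    cs <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    d2 <- outer((rs - r0)^2, (cs - c0)^2, `+`)
    m[rs, cs] <- m[rs, cs] | (d2 <= rad^2)
    m
  }
  switch(shape$type,
    disc = paint_disc(mask, r0, c0, shape$r),
    patch = {
      off <- matrix(c(0, 0, -0.6, 0.7, 0.7, 0.4), ncol = 2, byrow = TRUE) *
        shape$r
      for (i in seq_len(nrow(off)))
        mask <- paint_disc(mask, r0 + off[i, 1], c0 + off[i, 2], shape$r)
      mask
    },
    annulus = {
      rad <- shape$r_out
      rs <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
      cs <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
      d2 <- outer((rs - r0)^2, (cs - c0)^2, `+`)
      mask[rs, cs] <- mask[rs, cs] |
        (d2 <= shape$r_out^2 & d2 >= shape$r_in^2)
      mask
    },
    stop("unknown shape type"))
}

# shared placement logic for one class at a given raster scale.
# `scale` = raster pixels per heatmap pixel (1 for heatmaps,
# `stride` for full-resolution slides).
.plant_class <- function(spec, class_id, H, W, scale = 1) {
  shp <- .shape_params[[class_id]]
  shp_scaled <- lapply(shp, function(v) if (is.numeric(v)) v * scale else v)
  ay <- 0.45 * H; ax <- 0.45 * W
  s <- sqrt(spec$gm_fraction)
  margin <- (shp$bound + spec$boundary_margin_px) * scale
  min_dist <- (2 * shp$bound + spec$min_gap_px) * scale

  # physical gray-matter area from the raster mask
  gm_mask <- .ellipse_mask(H, W, ay * s, ax * s)
  px_mm <- (spec$mpp * (spec$width_px / W)) / 1000  # mm per raster pixel
  gm_area_mm2 <- sum(gm_mask) * px_mm^2
  n_total <- round(spec$class_densities[[class_id]] * gm_area_mm2)
  n_wm <- round(spec$white_matter_leak * n_total)
  n_gm <- n_total - n_wm

  in_gm <- function(r, c) .ellipse_test(r, c, H, W, ay * s, ax * s, margin)
  in_wm <- function(r, c) {
    .ellipse_test(r, c, H, W, ay, ax, margin) &
      !.ellipse_test(r, c, H, W, ay * s, ax * s, -margin)
  }
  pts_gm <- .place_points(n_gm, H, W, in_gm, min_dist)
  pts_all <- pts_gm
  if (n_wm > 0) {
    if (spec$gm_fraction >= 1)
      stop("white_matter_leak > 0 requires gm_fraction < 1")
    # white-matter deposits also keep the separation from gray-matter ones
    pts_wm <- .place_points(n_wm, H, W, function(r, c) {
      ok <- in_wm(r, c)
      if (ok && nrow(pts_all) > 0)
        ok <- min((pts_all[, 1] - r)^2 + (pts_all[, 2] - c)^2) >= min_dist^2
      ok
    }, min_dist)
    pts_all <- rbind(pts_gm, pts_wm)
  }
  dep_mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(pts_all)))
    dep_mask <- .paint_shape(dep_mask, pts_all[i, 1], pts_all[i, 2],
                             shp_scaled)
  list(tissue_mask = .ellipse_mask(H, W, ay, ax), gm_mask = gm_mask,
       deposit_mask = dep_mask, centroids = pts_all,
       count_total = nrow(pts_all), count_gm = n_gm,
       gm_area_mm2 = gm_area_mm2)
}

#' Generate a synthetic confidence heatmap with known ground truth
#'
#' Plants supra-threshold blobs directly at heatmap resolution (standing
#' in for sliding-window model inference, so the scoring stages can be
#' tested in isolation): deposit pixels get probability 0.95, tissue
#' background gets sub-threshold uniform noise on `[0, 0.3]`, and
#' non-tissue pixels are zero.
#'
#' @param spec a [slide_spec()].
#' @param class_id one of `"cored"`, `"diffuse"`, `"caa"`.
#' @return list with `heatmap` (numeric matrix in `[0, 1]`) and
#'   `ground_truth` (tissue / gray-matter / deposit masks at heatmap
#'   resolution, centroids, counts).
#' @export
generate_heatmap <- function(spec, class_id = "cored") {
  stopifnot(inherits(spec, "slide_spec"))
  class_id <- match.arg(class_id, .classes)
  hd <- heatmap_dim(spec)
  .with_seed(spec$seed * 131L + match(class_id, .classes), {
    gt <- .plant_class(spec, class_id, hd[1], hd[2], scale = 1)
    hm <- matrix(0, hd[1], hd[2])
    noise <- matrix(runif(prod(hd), 0, 0.3), hd[1], hd[2])
    hm[gt$tissue_mask] <- noise[gt$tissue_mask]
    hm[gt$deposit_mask] <- 0.95
    gt$class_id <- class_id
    list(heatmap = hm, ground_truth = gt)
  })
}

#' Render a synthetic slide image with known ground truth
#'
#' Draws the full-resolution RGB slide: near-white background, pale
#' hematoxylin-toned tissue ellipse, and DAB-brown deposits of the three
#' morphologies (compact discs for cored plaques, irregular pale patches
#' for diffuse plaques, rings for CAA), plus Gaussian pixel noise.
#' Deposit geometry matches the heatmap generator's placement rules
#' scaled to slide resolution.
#'
#' @param spec a [slide_spec()].
#' @return list with `image` (`H x W x 3` array in `[0, 1]`) and
#'   `ground_truth`: slide-resolution `tissue_mask`, `gm_mask`, per-class
#'   `deposit_masks`, `centroids`, `counts` (total and gray-matter-only).
#' @export
generate_slide_image <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  H <- spec$height_px; W <- spec$width_px
  sp <- spec$stain_params
  .with_seed(spec$seed * 131L, {
    scale <- spec$stride  # deposit sizes defined at heatmap scale
    gts <- lapply(.classes, function(cl)
      .plant_class(spec, cl, H, W, scale = scale))
    names(gts) <- .classes
    img <- array(rep(sp$background, each = H * W), dim = c(H, W, 3))
    tissue <- gts[[1]]$tissue_mask
    for (k in 1:3) {
      ch <- img[, , k]
      ch[tissue] <- sp$tissue[k]
      # large pale morphologies first so small dense ones stay visible
      for (cl in c("diffuse", "caa", "cored"))
        ch[gts[[cl]]$deposit_mask] <- sp[[cl]][k]
      img[, , k] <- ch
    }
    img <- img + array(rnorm(length(img), 0, sp$noise_sd), dim = dim(img))
    img <- pmin(pmax(img, 0), 1)
    gt <- list(
      tissue_mask = tissue, gm_mask = gts[[1]]$gm_mask,
      deposit_masks = lapply(gts, `[[`, "deposit_mask"),
      centroids = lapply(gts, `[[`, "centroids"),
      counts = vapply(gts, `[[`, 0, "count_total"),
      counts_gm = vapply(gts, `[[`, 0, "count_gm"))
    list(image = img, ground_truth = gt)
  })
}

#' Extract labeled classifier tiles from a synthetic slide
#'
#' Tiles the image on a non-overlapping grid and labels each tile
#' positive for a class when at least `overlap_threshold` pixels of that
#' class's deposit mask fall inside the tile (multilabel: a tile can be
#' positive for several pathologies).
#'
#' @param image RGB array from [generate_slide_image()].
#' @param ground_truth matching ground truth with `deposit_masks`.
#' @param tile_size tile side in pixels (default 256).
#' @param overlap_threshold minimum overlapping deposit pixels for a
#'   positive label (default 1).
#' @return list with `tiles`, `labels` (n x 3 0/1 matrix), `coords`.
#' @export
generate_labeled_tiles <- function(image, ground_truth, tile_size = 256L,
                                   overlap_threshold = 1L) {
  d <- dim(image)
  if (tile_size > d[1] || tile_size > d[2])
    stop("tile larger than image")
  tl <- tile_image(image, tile_size = tile_size, stride = tile_size)
  labels <- matrix(0L, nrow(tl$coords), length(.classes),
                   dimnames = list(NULL, .classes))
  for (cl in .classes) {
    m <- ground_truth$deposit_masks[[cl]]
    for (i in seq_len(nrow(tl$coords))) {
      y <- tl$coords$y0[i]; x <- tl$coords$x0[i]
      ys <- y:min(y + tile_size - 1L, d[1])
      xs <- x:min(x + tile_size - 1L, d[2])
      labels[i, cl] <- as.integer(sum(m[ys, xs]) >= overlap_threshold)
    }
  }
  list(tiles = tl$tiles, labels = labels, coords = tl$coords)
}

# pack an RGB array in [0,1] into the raw-byte tile format the C++
# classifier consumes
.tile_to_raw <- function(tile) {
  as.raw(pmin(pmax(round(tile * 255), 0), 255))
}

#' Generate a balanced set of labeled training tiles
#'
#' Draws standalone 256 x 256 tiles of tissue with independently sampled
#' class content (each pathology present with probability `p_positive`),
#' rendered with the stain palette of [default_stain_params()]. Tiles are
#' returned in the packed byte format consumed by [train_cnn()].
#'
#' @param n number of tiles.
#' @param tile_size side length (default 256).
#' @param p_positive per-class probability that a tile contains that
#'   pathology (default 0.4).
#' @param stain_params see [default_stain_params()].
#' @param seed RNG seed.
#' @return list with `tiles` (list of raw vectors), `labels`
#'   (`n x 3` 0/1 matrix), `tile_size`.
#' @export
generate_tile_set <- function(n, tile_size = 256L, p_positive = 0.4,
                              stain_params = default_stain_params(),
                              seed = 1L) {
  stopifnot(n >= 1, tile_size >= 64)
  sp <- stain_params
  scale <- tile_size / 16  # deposit sizes scale with tile size
  .with_seed(seed, {
    labels <- matrix(as.integer(runif(n * 3) < p_positive), n, 3,
                     dimnames = list(NULL, .classes))
    tiles <- vector("list", n)
    for (i in seq_len(n)) {
      base <- array(rep(sp$tissue, each = tile_size^2),
                    dim = c(tile_size, tile_size, 3))
      # paint large pale morphologies first so small dense ones stay visible
      for (cl in c("diffuse", "caa", "cored")) {
        if (labels[i, cl] == 0L) next
        shp <- lapply(.shape_params[[cl]], function(v)
          if (is.numeric(v)) v * scale else v)
        n_dep <- sample(1:3, 1)
        mask <- matrix(FALSE, tile_size, tile_size)
        for (j in seq_len(n_dep)) {
          r0 <- runif(1, tile_size * 0.25, tile_size * 0.75)
          c0 <- runif(1, tile_size * 0.25, tile_size * 0.75)
          mask <- .paint_shape(mask, r0, c0, shp)
        }
        for (k in 1:3) {
          ch <- base[, , k]
          ch[mask] <- sp[[cl]][k]
          base[, , k] <- ch
        }
      }
      base <- base + array(rnorm(length(base), 0, sp$noise_sd),
                           dim = dim(base))
      tiles[[i]] <- .tile_to_raw(pmin(pmax(base, 0), 1))
    }
    list(tiles = tiles, labels = labels, tile_size = as.integer(tile_size))
  })
}

#' Specification of a synthetic cohort
#'
#' Each slide gets one ordinal severity level (balanced across the
#' cohort) and per-class planted densities
#' `density_by_level + N(0, noise_sd)`, truncated at zero, so realized
#' density is monotone in the ordinal level up to noise -- the structure
#' that CERAD-like semi-quantitative scores impose on real cohorts.
#'
#' @param n_slides cohort size (must be >= the number of levels).
#' @param ordinal_levels ordered severity labels.
#' @param density_by_level named list (per class) of numeric vectors, one
#'   density per level, strictly increasing. Units: deposits per mm^2 of
#'   gray matter. The defaults are chosen so that even the `frequent`
#'   level stays well below the packing limit of the default slide
#'   geometry under the minimum-separation guarantee (diffuse deposits
#'   are large, so their feasible densities are lower).
#' @param noise_sd sd of the Gaussian density noise (same units; the
#'   default is 10% of the mean gap between adjacent cored levels).
#' @param slide_template [slide_spec()] supplying geometry and staining
#'   for every slide.
#' @param group_assignments optional data.frame of per-slide diagnosis
#'   flags / Reagan levels, recycled onto the cohort by row.
#' @param seed RNG seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_slides = 40L,
                        ordinal_levels = c("none", "sparse", "moderate",
                                           "frequent"),
                        density_by_level = list(
                          cored   = c(1, 8, 18, 30),
                          diffuse = c(0.5, 3, 7, 11),
                          caa     = c(0.3, 2, 5, 9)),
                        noise_sd = 1,
                        slide_template = slide_spec(),
                        group_assignments = NULL, seed = 1L) {
  if (length(ordinal_levels) < 1) stop("ordinal_levels must be non-empty")
  if (n_slides < length(ordinal_levels))
    stop("n_slides must be at least the number of ordinal levels")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  for (cl in names(density_by_level)) {
    d <- density_by_level[[cl]]
    if (length(d) != length(ordinal_levels))
      stop("density_by_level$", cl, " must have one value per level")
    if (any(diff(d) <= 0))
      stop("density_by_level$", cl,
           " must be strictly increasing along the ordinal levels")
  }
  structure(list(n_slides = as.integer(n_slides),
                 ordinal_levels = ordinal_levels,
                 density_by_level = density_by_level, noise_sd = noise_sd,
                 slide_template = slide_template,
                 group_assignments = group_assignments,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param classes which pathology classes to realize (default all three).
#' @return list with `slide_specs` (per-slide [slide_spec()] carrying the
#'   realized densities) and `records`, a data.frame with one row per
#'   slide: ordinal level and realized density per class, plus any
#'   planted group assignments.
#' @export
generate_cohort <- function(spec, classes = .classes) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- match.arg(classes, .classes, several.ok = TRUE)
  n <- spec$n_slides
  L <- length(spec$ordinal_levels)
  .with_seed(spec$seed * 977L, {
    levels_idx <- sample(rep_len(seq_len(L), n))   # balanced, shuffled
    records <- data.frame(slide_id = sprintf("S%03d", seq_len(n)),
                          stringsAsFactors = FALSE)
    dens <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
    for (cl in classes) {
      base <- spec$density_by_level[[cl]][levels_idx]
      dens[, cl] <- pmax(0, base + rnorm(n, 0, spec$noise_sd))
      records[[paste0("level_", cl)]] <-
        factor(spec$ordinal_levels[levels_idx],
               levels = spec$ordinal_levels, ordered = TRUE)
      records[[paste0("density_", cl)]] <- dens[, cl]
    }
    slide_specs <- lapply(seq_len(n), function(i) {
      s <- spec$slide_template
      cd <- s$class_densities
      cd[classes] <- dens[i, classes]
      s$class_densities <- cd
      s$seed <- spec$seed * 1000L + i
      s
    })
    if (!is.null(spec$group_assignments)) {
      ga <- spec$group_assignments
      idx <- rep_len(seq_len(nrow(ga)), n)
      records <- cbind(records, ga[idx, , drop = FALSE])
      rownames(records) <- NULL
    }
    list(slide_specs = slide_specs, records = records)
  })
}
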