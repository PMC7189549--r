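## Pipeline orchestration and artifact I/O: heatmap TIFFs, mask PNGs,
## score CSVs, region annotations, YAML specs, and the end-to-end
## synthetic / manifest-driven run with provenance manifest.

#' Write / read a confidence heatmap as 32-bit float TIFF
#'
#' Channels are stored as a multi-sample TIFF; the sliding-window stride
#' and window size are recorded in a YAML sidecar (`<path>.meta.yaml`).
#'
#' @param heatmap `confidence_heatmap` array (or plain matrix/array).
#' @param path output path.
#' @export
write_heatmap <- function(heatmap, path) {
  stride <- attr(heatmap, "stride"); window <- attr(heatmap, "window")
  if (is.null(stride)) stride <- 16L
  if (is.null(window)) window <- 256L
  arr <- unclass(heatmap)
  attributes(arr) <- list(dim = dim(arr))
  tiff::writeTIFF(arr, path, bits.per.sample = 32L)
  yaml::write_yaml(list(stride = stride, window = window),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_heatmap
#' @return for `read_heatmap`, the heatmap array with `stride` /
#'   `window` attributes restored.
#' @export
read_heatmap <- function(path) {
  img <- tiff::readTIFF(path)
  stride <- 16L; window <- 256L
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    stride <- as.integer(meta$stride); window <- as.integer(meta$window)
  }
  arr <- img
  attributes(arr) <- list(dim = dim(img))
  if (length(dim(arr)) == 3 && dim(arr)[3] == 3)
    dimnames(arr) <- list(NULL, NULL, c("cored", "diffuse", "caa"))
  structure(arr, stride = stride, window = window,
            class = "confidence_heatmap")
}

#' Write / read a binary mask as single-channel PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @return for `read_mask`, a logical matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write / read score tables as CSV
#'
#' Lossless round trip of `score_result` / `fov_windows` tables;
#' numeric columns are written with 15 significant digits.
#'
#' @param results data.frame of scores.
#' @param path CSV path.
#' @export
write_scores <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                scientific = TRUE,
                                                trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @param required_cols columns that must be present (schema check).
#' @return for `read_scores`, the parsed data.frame.
#' @export
read_scores <- function(path, required_cols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(df))
    if (length(miss))
      stop("malformed score CSV ", path, ": missing column(s) ",
           paste(miss, collapse = ", "))
  }
  df
}

#' Serialize / restore a slide spec as YAML
#'
#' @param spec a [slide_spec()].
#' @param path YAML path.
#' @export
write_slide_spec <- function(spec, path) {
  stopifnot(inherits(spec, "slide_spec"))
  x <- unclass(spec)
  x$class_densities <- as.list(x$class_densities)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_slide_spec
#' @return for `read_slide_spec`, the restored `slide_spec`.
#' @export
read_slide_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$class_densities <- unlist(x$class_densities)
  x$stain_params <- lapply(x$stain_params, unlist)
  do.call(slide_spec, x)
}

# basic self-intersection test for a polygon ring (O(n^2) segments)
.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  inter <- function(p1, p2, p3, p4) {
    d <- function(a, b, c)
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # shared endpoint with closing edge
      if (inter(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

#' Load a region annotation as a heatmap-resolution mask
#'
#' Accepts either a mask PNG at slide resolution (downsampled to the
#' heatmap grid by window-center sampling) or a JSON polygon annotation:
#' `{"polygons": [[[x, y], ...], ...]}` with vertices in slide pixels
#' (x = column, y = row). Polygons are rasterized by testing the
#' window-center of each heatmap pixel for membership (even-odd rule),
#' which is equivalent to slide-resolution rasterization followed by
#' nearest-neighbour downsampling.
#'
#' @param file `.png` mask or `.json` polygon file.
#' @param spec a [slide_spec()], or any list with `height_px`,
#'   `width_px`, `window`, `stride` describing the heatmap geometry.
#' @return logical heatmap-resolution matrix with attribute `area_px`.
#' @export
load_region_annotation <- function(file, spec) {
  hh <- (spec$height_px - spec$window) %/% spec$stride + 1L
  hw <- (spec$width_px - spec$window) %/% spec$stride + 1L
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    m <- read_mask(file)
    if (nrow(m) == hh && ncol(m) == hw) mask <- m
    else if (nrow(m) == spec$height_px && ncol(m) == spec$width_px)
      mask <- downsample_mask(m, window = spec$window, stride = spec$stride)
    else stop("mask dimensions match neither the slide nor the heatmap")
  } else {
    ann <- jsonlite::fromJSON(file, simplifyVector = FALSE)
    polys <- ann$polygons
    if (is.null(polys) || length(polys) == 0) {
      warning("empty annotation: returning an empty mask")
      mask <- matrix(FALSE, hh, hw)
    } else {
      centers_y <- (seq_len(hh) - 1L) * spec$stride + spec$window / 2
      centers_x <- (seq_len(hw) - 1L) * spec$stride + spec$window / 2
      pts <- cbind(rep(centers_x, each = hh), rep(centers_y, times = hw))
      inside <- rep(FALSE, nrow(pts))
      for (p in polys) {
        poly <- if (is.matrix(p)) p
                else do.call(rbind, lapply(p, function(v)
                  as.numeric(unlist(v))))
        if (.polygon_self_intersects(poly))
          stop("self-intersecting polygon rejected")
        inside <- inside | mgcv::in.out(poly, pts)
      }
      mask <- matrix(inside, hh, hw)
    }
  }
  attr(mask, "area_px") <- sum(mask)
  mask
}

.stage_order <- c("synth", "heatmap", "score", "gm-score", "fov", "stats")

#' Run the scoring pipeline end to end
#'
#' Two entry paths: a synthetic cohort (`cohort` spec; heatmaps are
#' generated directly at heatmap resolution with ground truth) or an
#' input manifest (CSV listing per-slide heatmap TIFFs, optional
#' gray-matter mask PNGs, and ordinal metadata). Enabled stages run in
#' dependency order; every artifact lands in `out_dir` and is
#' checksummed into `manifest.json`.
#'
#' @param cohort a [cohort_spec()] (synthetic path), or `NULL`.
#' @param manifest path to a manifest CSV with columns `slide_id`,
#'   `heatmap` (TIFF path), optional `gm_mask` (PNG path) and
#'   `level_<class>` columns, or `NULL`.
#' @param out_dir output directory (created if missing).
#' @param stages subset of `c("score", "gm-score", "fov", "stats")`.
#' @param classes pathology classes to analyze.
#' @param params [morphology_params()].
#' @param fov [fov_config()] (used by the `fov` stage).
#' @param fov_n top-n values for the convergence table.
#' @param seed seed for the synthetic path.
#' @return (invisibly) list with `scores`, `records`, `fov`,
#'   `convergence`, `stats`, `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, manifest = NULL,
                         out_dir = tempfile("plaquescope_run_"),
                         stages = c("score", "gm-score", "fov", "stats"),
                         classes = c("cored", "diffuse", "caa"),
                         params = morphology_params(), fov = fov_config(),
                         fov_n = c(1L, 3L, 5L, 7L, 9L, 11L, 13L, 15L),
                         seed = 1L) {
  if (is.null(cohort) == is.null(manifest))
    stop("exactly one of `cohort` (synthetic) or `manifest` must be given")
  stages <- match.arg(stages, .stage_order[-(1:2)], several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  heatmaps <- list()   # slide -> class -> matrix
  tissue <- list(); gm <- list()
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_spec"))
    cohort$seed <- as.integer(seed)
    gen <- generate_cohort(cohort, classes = classes)
    records <- gen$records
    for (i in seq_along(gen$slide_specs)) {
      sid <- records$slide_id[i]
      hm <- lapply(setNames(classes, classes), function(cl)
        generate_heatmap(gen$slide_specs[[i]], cl))
      heatmaps[[sid]] <- lapply(hm, `[[`, "heatmap")
      tissue[[sid]] <- hm[[1]]$ground_truth$tissue_mask
      gm[[sid]] <- hm[[1]]$ground_truth$gm_mask
    }
  } else {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!"slide_id" %in% names(man) || !"heatmap" %in% names(man))
      stop("manifest must have slide_id and heatmap columns")
    missing_files <- man$heatmap[!file.exists(man$heatmap)]
    if (length(missing_files))
      stop("missing heatmap file(s): ",
           paste(missing_files, collapse = ", "))
    records <- man[, !(names(man) %in% c("heatmap", "gm_mask")),
                   drop = FALSE]
    for (i in seq_len(nrow(man))) {
      sid <- man$slide_id[i]
      arr <- read_heatmap(man$heatmap[i])
      heatmaps[[sid]] <- lapply(setNames(seq_along(classes), classes),
                                function(k) arr[, , k])
      # convention: tissue = any window the model scored
      tissue[[sid]] <- Reduce(`|`, lapply(heatmaps[[sid]],
                                          function(m) m > 0))
      if ("gm_mask" %in% names(man) && nzchar(man$gm_mask[i]) &&
          file.exists(man$gm_mask[i])) {
        m <- read_mask(man$gm_mask[i])
        if (!identical(dim(m), dim(tissue[[sid]])))
          stop("gm mask for ", sid, " is not at heatmap resolution")
        gm[[sid]] <- m
      }
    }
  }
  slide_ids <- names(heatmaps)
  outputs <- character(0)
  scores <- NULL; fov_tabs <- list(); convergence <- list(); stats <- list()

  score_one <- function(region_of) {
    do.call(rbind, lapply(slide_ids, function(sid)
      do.call(rbind, lapply(classes, function(cl)
        compute_score(heatmaps[[sid]][[cl]], cl, params,
                      region = region_of(sid), slide_id = sid,
                      region_label = if (identical(region_of, tissue_of))
                        "whole_tissue" else "gray_matter")))))
  }
  tissue_of <- function(sid) tissue[[sid]]
  gm_of <- function(sid) gm[[sid]] & tissue[[sid]]

  if ("score" %in% stages) {
    scores <- score_one(tissue_of)
    if ("gm-score" %in% stages) {
      if (length(gm) == 0)
        stop("gm-score stage enabled but no gray-matter masks available")
      scores <- rbind(scores, score_one(gm_of))
    }
    p <- file.path(out_dir, "scores.csv")
    write_scores(scores, p); outputs <- c(outputs, p)
  } else if ("gm-score" %in% stages) {
    stop("gm-score stage requires the score stage")
  }

  level_col <- function(cl) {
    nm <- paste0("level_", cl)
    if (nm %in% names(records)) records[[nm]] else NULL
  }

  if ("fov" %in% stages) {
    for (cl in classes) {
      fov_tabs[[cl]] <- lapply(setNames(slide_ids, slide_ids),
                               function(sid)
        compute_fov_scores(heatmaps[[sid]][[cl]], cl, params,
                           tissue_mask = tissue[[sid]], config = fov))
      all_win <- do.call(rbind, lapply(slide_ids, function(sid) {
        w <- fov_tabs[[cl]][[sid]]
        if (nrow(w)) cbind(slide_id = sid, class = cl, w) else NULL
      }))
      if (!is.null(all_win)) {
        p <- file.path(out_dir, paste0("fov_windows_", cl, ".csv"))
        write_scores(all_win, p); outputs <- c(outputs, p)
      }
      lev <- level_col(cl)
      if (!is.null(lev) && !is.null(scores)) {
        wt <- scores[scores$class == cl & scores$region == "whole_tissue", ]
        wt <- wt$cnn_score[match(slide_ids, wt$slide_id)]
        conv <- convergence_table(fov_tabs[[cl]], lev, wt, n_values = fov_n)
        convergence[[cl]] <- conv
        p <- file.path(out_dir, paste0("convergence_", cl, ".csv"))
        utils::write.csv(conv$table, p, row.names = FALSE)
        outputs <- c(outputs, p)
      }
    }
  }

  if ("stats" %in% stages) {
    if (is.null(scores)) {
      existing <- file.path(out_dir, "scores.csv")
      if (!file.exists(existing))
        stop("stats stage requires the score stage (no scores.csv found)")
      scores <- read_scores(existing,
                            c("slide_id", "class", "region", "cnn_score"))
    }
    report <- character(0)
    for (cl in classes) {
      lev <- level_col(cl)
      if (is.null(lev)) next
      wt <- scores[scores$class == cl & scores$region == "whole_tissue", ]
      s <- wt$cnn_score[match(records$slide_id, wt$slide_id)]
      cmp <- anova_tukey(s, lev)
      rho <- spearman_ordinal(s, lev)
      kw <- kruskal_wallis(s, lev)
      stats[[cl]] <- list(anova = cmp, spearman = rho, kruskal = kw)
      report <- c(report,
        sprintf("[%s] ANOVA F = %.3g (p = %.3g); Spearman rho = %.3f; Kruskal-Wallis p = %.3g",
                cl, cmp$f, cmp$p, rho, kw$p))
    }
    p <- file.path(out_dir, "stats_report.txt")
    writeLines(report, p); outputs <- c(outputs, p)
  }

  man_obj <- list(
    package_version = as.character(utils::packageVersion("plaquescope")),
    seed = seed, stages = stages, timestamp = format(Sys.time()),
    outputs = lapply(setNames(outputs, basename(outputs)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(man_obj, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scores = scores, records = records, fov = fov_tabs,
                 convergence = convergence, stats = stats,
                 manifest = man_obj, out_dir = out_dir))
}
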