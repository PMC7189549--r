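## Compact multilabel CNN: six 3x3-conv + max-pool blocks, dense layers
## of 512 and 100 units, and three sigmoid outputs (one independent
## probability per amyloid pathology). Numerics live in src/; this file
## is the model-object surface (build / train / predict / evaluate /
## sliding-window inference).

#' CNN architecture configuration
#'
#' Fixed skeleton: `length(channels)` convolutional blocks (3x3 kernels,
#' zero padding, ReLU, 2x2 max pooling) followed by ReLU dense layers
#' and a sigmoid output per class. Input spatial size must be divisible
#' by `2^length(channels)`; with the defaults 256 is pooled down to 4
#' before flattening. The channel progression and activation are
#' configuration, not architecture: only the layer counts and the
#' 512/100 dense widths are structural.
#'
#' @param input_size square input side in pixels (default 256).
#' @param channels per-block output channel counts.
#' @param dense hidden dense-layer widths (default `c(512, 100)`).
#' @param classes output class names (default cored, diffuse, caa).
#' @return a `cnn_config` object.
#' @export
cnn_config <- function(input_size = 256L,
                       channels = c(8L, 16L, 16L, 32L, 32L, 64L),
                       dense = c(512L, 100L),
                       classes = c("cored", "diffuse", "caa")) {
  n_blocks <- length(channels)
  if (input_size %% 2^n_blocks != 0)
    stop("input_size must be divisible by 2^", n_blocks)
  spatial <- input_size %/% 2^n_blocks
  if (spatial < 1) stop("too many pooling stages for this input size")
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 dense = as.integer(dense), classes = classes,
                 n_classes = length(classes),
                 flat_size = as.integer(spatial^2 * channels[n_blocks]),
                 final_spatial = as.integer(spatial)),
            class = "cnn_config")
}

#' Build an untrained CNN
#'
#' He-normal weight initialization (sd `sqrt(2 / fan_in)`), zero biases;
#' identical seed gives identical initial parameters.
#'
#' @param config a [cnn_config()].
#' @param seed RNG seed for the initialization.
#' @return object of class `plaque_cnn` with elements `config`, `params`
#'   and `history`.
#' @export
build_cnn <- function(config = cnn_config(), seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  .with_seed(seed, {
    conv_w <- list(); conv_b <- list()
    c_in <- 3L
    for (c_out in config$channels) {
      fan_in <- c_in * 9L
      conv_w[[length(conv_w) + 1L]] <-
        matrix(rnorm(c_out * fan_in, 0, sqrt(2 / fan_in)), c_out, fan_in)
      conv_b[[length(conv_b) + 1L]] <- numeric(c_out)
      c_in <- c_out
    }
    dense_w <- list(); dense_b <- list()
    d_in <- config$flat_size
    for (d_out in c(config$dense, config$n_classes)) {
      dense_w[[length(dense_w) + 1L]] <-
        matrix(rnorm(d_out * d_in, 0, sqrt(2 / d_in)), d_out, d_in)
      dense_b[[length(dense_b) + 1L]] <- numeric(d_out)
      d_in <- d_out
    }
    structure(list(config = config,
                   params = list(conv_w = conv_w, conv_b = conv_b,
                                 dense_w = dense_w, dense_b = dense_b),
                   history = NULL),
              class = "plaque_cnn")
  })
}

#' @export
print.plaque_cnn <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(unlist(x$params, recursive = FALSE), length, 0L))
  cat(sprintf(
    "Multilabel CNN: %d conv blocks (%s), dense %s -> %d sigmoid outputs\n",
    length(cfg$channels), paste(cfg$channels, collapse = "-"),
    paste(cfg$dense, collapse = "-"), cfg$n_classes))
  cat(sprintf("  input %dx%dx3, %s parameters%s\n", cfg$input_size,
              cfg$input_size, format(n_par, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  if (!is.null(x$history)) {
    cat("  final epoch loss:",
        signif(utils::tail(x$history$loss, 1), 4), "\n")
  }
  invisible(x)
}

# normalize tile input: list of raw vectors, or list/array of RGB arrays
.as_raw_tiles <- function(tiles, input_size) {
  if (is.list(tiles) && !is.null(tiles$tiles)) tiles <- tiles$tiles
  lapply(tiles, function(t) {
    if (is.raw(t)) {
      if (length(t) != input_size^2 * 3)
        stop("raw tile length does not match the model input size")
      return(t)
    }
    if (!identical(dim(t)[1:2], c(input_size, input_size)))
      stop("tile dimensions do not match the model input size (",
           input_size, ")")
    .tile_to_raw(t)
  })
}

#' Train the CNN on labeled tiles
#'
#' Mini-batch Adam on mean binary cross-entropy across the class
#' outputs. A fraction of the tiles is held out for validation; the
#' fitted model carries per-epoch training loss and final per-class
#' validation AUROC. Determinism is metric-level: the same seed gives
#' the same shuffles and initial state.
#'
#' @param model a [build_cnn()] object.
#' @param tiles list of tiles (raw vectors as produced by
#'   [generate_tile_set()], or RGB arrays), or the full list returned by
#'   [generate_tile_set()].
#' @param labels `n x n_classes` 0/1 matrix (taken from `tiles` when it
#'   is a `generate_tile_set()` result and `labels` is missing).
#' @param epochs training epochs (0 returns the model unchanged).
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param validation_split fraction of tiles held out (0 disables).
#' @param seed RNG seed for the split and shuffles.
#' @return the trained `plaque_cnn` with a `history` element:
#'   `loss` (per epoch), `val` (per-class AUROC data.frame or NULL),
#'   `val_idx`.
#' @export
train_cnn <- function(model, tiles, labels = NULL, epochs = 2L,
                      batch_size = 16L, lr = 2e-3,
                      validation_split = 0.2, seed = 1L) {
  stopifnot(inherits(model, "plaque_cnn"), epochs >= 0, batch_size >= 1,
            validation_split >= 0, validation_split < 1)
  if (is.null(labels) && is.list(tiles) && !is.null(tiles$labels))
    labels <- tiles$labels
  raws <- .as_raw_tiles(tiles, model$config$input_size)
  n <- length(raws)
  if (n == 0) stop("empty training set")
  labels <- as.matrix(labels)
  if (nrow(labels) != n || ncol(labels) != model$config$n_classes)
    stop("labels must be an n x ", model$config$n_classes, " 0/1 matrix")
  if (nrow(unique(labels)) < 2)
    stop("training labels are all identical: nothing to learn")
  if (epochs == 0) {
    model$history <- list(loss = numeric(0), val = NULL, val_idx = integer(0))
    return(model)
  }
  .with_seed(seed, {
    n_val <- floor(validation_split * n)
    val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    n_tr <- length(tr_idx)
    order_mat <- vapply(seq_len(epochs), function(e) sample.int(n_tr),
                        integer(n_tr))
    fit <- .cpp_cnn_train(model$params, raws[tr_idx],
                          labels[tr_idx, , drop = FALSE],
                          model$config$input_size, 3L, as.integer(epochs),
                          as.integer(batch_size), lr, 0.9, 0.999, 1e-8,
                          order_mat)
    model$params <- fit$params
    val <- NULL
    if (length(val_idx) > 1) {
      val <- evaluate_cnn(model, raws[val_idx],
                          labels[val_idx, , drop = FALSE])
    }
    model$history <- list(loss = fit$loss, val = val, val_idx = val_idx)
    model
  })
}

#' @param object a trained `plaque_cnn`.
#' @param tiles tiles as in [train_cnn()].
#' @param ... unused.
#' @return matrix `n x n_classes` of class probabilities.
#' @rdname train_cnn
#' @export
predict.plaque_cnn <- function(object, tiles, ...) {
  raws <- .as_raw_tiles(tiles, object$config$input_size)
  out <- .cpp_cnn_predict(object$params, raws, object$config$input_size, 3L)
  colnames(out) <- object$config$classes
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Tie-corrected AUROC computed as the normalized Mann-Whitney U
#' statistic `U / (n_pos * n_neg)`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcomes.
#' @return AUROC, or NA when one outcome class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-interpolated AP: the mean of precision evaluated at each
#' positive, with ties in score averaged.
#'
#' @inheritParams auroc
#' @return AP in `[0, 1]`, or NA when no positives exist.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) return(NA_real_)
  ord <- order(-scores)
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Evaluate per-class ROC / precision-recall performance
#'
#' @param model a trained `plaque_cnn`.
#' @param tiles,labels evaluation tiles and 0/1 label matrix.
#' @return data.frame: `class`, `auroc`, `average_precision`, `n_pos`,
#'   `n_neg` (NA metrics for classes with a single outcome).
#' @export
evaluate_cnn <- function(model, tiles, labels) {
  probs <- predict(model, tiles)
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == nrow(probs))
  data.frame(
    class = model$config$classes,
    auroc = vapply(seq_len(ncol(probs)), function(k)
      auroc(probs[, k], labels[, k]), 0),
    average_precision = vapply(seq_len(ncol(probs)), function(k)
      average_precision(probs[, k], labels[, k]), 0),
    n_pos = colSums(labels == 1), n_neg = colSums(labels == 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Sliding-window confidence heatmap
#'
#' Slides the classifier window across the slide at the given stride;
#' heatmap pixel `(i, j)` holds the class probabilities of the window
#' with top-left slide pixel `((i-1)*stride + 1, (j-1)*stride + 1)`, so
#' the heatmap has `floor((H - window)/stride) + 1` rows. Windows with
#' tissue-mask coverage below `min_tissue_frac` are skipped and left at
#' zero.
#'
#' @param model a trained `plaque_cnn`.
#' @param image RGB array `H x W x 3` in `[0, 1]`.
#' @param tissue_mask logical `H x W` matrix, or `NULL` to score every
#'   window.
#' @param stride window stride in slide pixels (default 16).
#' @param min_tissue_frac minimum tissue coverage to score a window
#'   (default 0.5; 0 disables skipping).
#' @return numeric array `hh x hw x n_classes` of class
#'   `confidence_heatmap`, with attributes `stride`, `window`, `classes`.
#' @export
sliding_window_heatmap <- function(model, image, tissue_mask = NULL,
                                   stride = 16L, min_tissue_frac = 0.5) {
  stopifnot(inherits(model, "plaque_cnn"), stride >= 1)
  win <- model$config$input_size
  d <- dim(image)
  if (d[1] < win || d[2] < win)
    stop("image smaller than the classifier window (", win, ")")
  tm <- if (is.null(tissue_mask)) matrix(0L, 0, 0)
        else matrix(as.integer(tissue_mask), d[1], d[2])
  hm <- .cpp_sliding_window(model$params, image, tm, as.integer(stride),
                            win, min_tissue_frac)
  dimnames(hm) <- list(NULL, NULL, model$config$classes)
  structure(hm, stride = as.integer(stride), window = win,
            classes = model$config$classes, class = "confidence_heatmap")
}

#' Save / load a trained CNN checkpoint
#'
#' Standard R serialization of the parameter list and configuration.
#'
#' @param model a `plaque_cnn`.
#' @param path file path (`.rds`).
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "plaque_cnn"))
  saveRDS(unclass(model), path)
}

#' @rdname save_cnn
#' @return for `load_cnn`, the restored `plaque_cnn`.
#' @export
load_cnn <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), !is.null(obj$params), !is.null(obj$config))
  structure(obj, class = "plaque_cnn")
}
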