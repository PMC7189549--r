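# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

# stack-based flood fill; returns component count and sorted sizes
flood_fill_components <- function(raster, connectivity = 8) {
  H <- nrow(raster); W <- ncol(raster)
  seen <- matrix(FALSE, H, W)
  offs <- if (connectivity == 8)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  sizes <- integer(0)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!raster[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE; size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            raster[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(count = length(sizes), sizes = sort(sizes))
}

# one-way ANOVA F by explicit sums of squares
anova_f_oracle <- function(scores, groups) {
  groups <- as.factor(groups)
  gm <- mean(scores)
  means <- tapply(scores, groups, mean)
  ns <- tapply(scores, groups, length)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((scores - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(scores) - nlevels(groups)
  (ss_between / df1) / (ss_within / df2)
}

# pooled-variance two-sample t by the textbook formula
t_oracle <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Kruskal-Wallis H with tie correction, by the rank-sum formula
kw_oracle <- function(scores, groups) {
  groups <- as.factor(groups)
  n <- length(scores)
  r <- rank(scores)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(scores)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Spearman rho as Pearson correlation of midranks
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# AUROC by explicit enumeration of positive/negative pairs
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# plant supra-threshold discs on an otherwise-zero heatmap
plant_discs <- function(H, W, centers, radius = 2, value = 0.95) {
  hm <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    for (r in max(1, r0 - radius):min(H, r0 + radius))
      for (c in max(1, c0 - radius):min(W, c0 + radius))
        if ((r - r0)^2 + (c - c0)^2 <= radius^2) hm[r, c] <- value
  }
  hm
}

# a small CNN configuration for fast unit tests (64-px input)
tiny_cnn_config <- function() {
  cnn_config(input_size = 64L, channels = c(2L, 2L, 2L, 4L, 4L, 4L),
             dense = c(16L, 8L))
}
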