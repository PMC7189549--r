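## Cohort statistics: grouping by diagnosis / NIA-Reagan level and the
## standard comparisons (one-way ANOVA + Tukey HSD, two-sided t-test,
## Kruskal-Wallis, Spearman rank correlation against ordinal scores).

.stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-4) "****" else if (p < 1e-3) "***"
  else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Assign slides to diagnosis comparison groups
#'
#' Builds the diagnosis groupings used for score comparisons:
#' `control` (no neurodegenerative pathology), `pure_AD` (AD with no
#' secondary diagnosis; probable/possible AD counts as AD), `all_AD`
#' (any case with AD pathology), `AD_TDP` (AD with TDP-43-positive
#' inclusions) and `AD_LBD` (AD with limbic/neocortical Lewy body
#' disease). Amygdala-predominant LBD does not count toward the LBD
#' group (but such cases remain in `all_AD`), and cases that were
#' clinically control yet showed AD pathology at autopsy are excluded
#' by default (set `exclude_clinical_controls = FALSE` to keep them as
#' pure AD).
#'
#' @param records data.frame with `slide_id` and logical columns
#'   `control`, `ad`, `tdp`, `lbd`, `amygdala_lbd`,
#'   `clinical_control_ad`.
#' @param exclude_clinical_controls drop clinically-normal-with-AD
#'   cases (default TRUE).
#' @return named list of slide-id character vectors, one per group.
#' @export
assign_diagnosis_groups <- function(records,
                                    exclude_clinical_controls = TRUE) {
  need <- c("slide_id", "control", "ad", "tdp", "lbd", "amygdala_lbd",
            "clinical_control_ad")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ",
                         paste(miss, collapse = ", "))
  if (any(records$control & records$ad))
    stop("a record flagged control cannot also carry an AD flag")
  r <- records
  if (exclude_clinical_controls) r <- r[!r$clinical_control_ad, ]
  ad <- r$ad | (!exclude_clinical_controls & r$clinical_control_ad)
  list(
    control = r$slide_id[r$control],
    pure_AD = r$slide_id[ad & !r$tdp & !r$lbd & !r$amygdala_lbd],
    all_AD  = r$slide_id[ad],
    AD_TDP  = r$slide_id[ad & r$tdp],
    AD_LBD  = r$slide_id[ad & r$lbd])
}

#' Merge NIA-Reagan likelihood levels into three ordered groups
#'
#' The `no` and `low` likelihood levels are pooled (they are typically
#' too small to analyze separately), giving the ordered grouping
#' `no/low < intermediate < high`.
#'
#' @param reagan character or factor of levels `no`, `low`,
#'   `intermediate`, `high` (NA allowed; dropped with a warning).
#' @return ordered factor of the same length (NA for missing input).
#' @export
merge_reagan_levels <- function(reagan) {
  x <- as.character(reagan)
  if (length(x) == 0)
    return(factor(character(0),
                  levels = c("no/low", "intermediate", "high"),
                  ordered = TRUE))
  bad <- !is.na(x) & !x %in% c("no", "low", "intermediate", "high")
  if (any(bad)) stop("unknown Reagan level(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  if (anyNA(x)) warning(sum(is.na(x)), " record(s) without a Reagan ",
                        "level dropped from the grouping")
  merged <- ifelse(x %in% c("no", "low"), "no/low", x)
  factor(merged, levels = c("no/low", "intermediate", "high"),
         ordered = TRUE)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Classical equal-variance one-way ANOVA (Welch's variant behind
#' `welch = TRUE`) with Tukey's honestly-significant-difference adjusted
#' p-values for every group pair; pairs of neighbouring levels in the
#' supplied factor order are flagged as adjacent, matching how ordinal
#' severity groups are reported.
#'
#' @param scores numeric response.
#' @param groups factor (order defines adjacency).
#' @param alpha significance level (default 0.05).
#' @param welch use Welch's unequal-variance ANOVA for the omnibus test.
#' @return object of class `group_comparison`: `f`, `p`, `n_per_group`,
#'   `tukey` (data.frame: pair, diff, p_adj, adjacent, stars), `alpha`,
#'   and the input data for plotting.
#' @export
anova_tukey <- function(scores, groups, alpha = 0.05, welch = FALSE) {
  groups <- droplevels(as.factor(groups))
  keep <- stats::complete.cases(scores, groups)
  scores <- scores[keep]; groups <- droplevels(groups[keep])
  n_per <- table(groups)
  if (length(n_per) < 2) stop("at least two groups required")
  if (any(n_per < 2)) stop("every group needs at least two observations")
  if (all(tapply(scores, groups, stats::var) == 0))
    stop("zero within-group variance everywhere: ANOVA undefined")
  fit <- stats::aov(scores ~ groups)
  if (welch) {
    ow <- stats::oneway.test(scores ~ groups, var.equal = FALSE)
    f <- unname(ow$statistic); p <- ow$p.value
  } else {
    s <- summary(fit)[[1]]
    f <- s$`F value`[1]; p <- s$`Pr(>F)`[1]
  }
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- rownames(tk)
  lv <- levels(groups)
  split_pair <- strsplit(pairs, "-", fixed = TRUE)
  adjacent <- vapply(split_pair, function(pr)
    abs(match(pr[1], lv) - match(pr[2], lv)) == 1L, TRUE)
  tukey <- data.frame(pair = pairs, diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], adjacent = adjacent,
                      stars = vapply(tk[, "p adj"], .stars, ""),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(f = f, p = p, n_per_group = n_per, tukey = tukey,
                 alpha = alpha, welch = welch,
                 data = data.frame(score = scores, group = groups)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F = %.3g, p = %.3g %s\n",
              if (x$welch) " (Welch)" else "", x$f, x$p, .stars(x$p)))
  cat("Group sizes:", paste(names(x$n_per_group), x$n_per_group,
                            sep = "=", collapse = ", "), "\n")
  cat("Tukey HSD adjusted p-values:\n")
  tk <- x$tukey
  tk$diff <- signif(tk$diff, 3); tk$p_adj <- signif(tk$p_adj, 3)
  print(tk, row.names = FALSE)
  invisible(x)
}

#' @export
plot.group_comparison <- function(x, main = "", ylab = "CNN score", ...) {
  graphics::boxplot(score ~ group, data = x$data, range = 1.5,
                    outline = FALSE, main = main, ylab = ylab,
                    medcol = "red", ...)
  st <- graphics::boxplot(score ~ group, data = x$data, range = 1.5,
                          plot = FALSE)
  if (length(st$out))
    graphics::points(st$group, st$out, pch = 3, col = "red")
  invisible(x)
}

#' Two-sided independent-sample t-test (pooled variance)
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `statistic`, `p`, `df`. Two constant equal samples
#'   give `t = 0, p = 1` by convention.
#' @export
two_sided_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  res <- tryCatch(stats::t.test(a, b, var.equal = TRUE), error = function(e) NULL)
  if (is.null(res)) {   # both samples constant
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, p = 1, df = length(a) + length(b) - 2))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2))
  }
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with chi-square p-value; the rank-based
#' alternative used when score distributions carry strong outliers.
#'
#' @param scores numeric response.
#' @param groups factor.
#' @return list with `statistic` (H), `p`, `df`; all-tied data gives
#'   `NA` statistic and p (test undefined).
#' @export
kruskal_wallis <- function(scores, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("at least two groups required")
  if (length(unique(scores)) == 1)
    return(list(statistic = NA_real_, p = NA_real_,
                df = nlevels(groups) - 1L))
  res <- stats::kruskal.test(scores, groups)
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Spearman rank correlation between scores and ordinal labels
#'
#' Tie-corrected (midrank) Spearman rho, the agreement measure between
#' continuous quantitative scores and semi-quantitative ordinal
#' categories.
#'
#' @param scores numeric.
#' @param labels ordinal labels (ordered factor, or numeric ranks).
#' @return rho, or `NA` when either input is constant (undefined).
#' @export
spearman_ordinal <- function(scores, labels) {
  if (length(scores) < 3) stop("at least 3 observations required")
  lab <- if (is.numeric(labels)) labels else as.integer(as.factor(labels))
  if (length(lab) != length(scores))
    stop("scores and labels differ in length")
  keep <- stats::complete.cases(scores, lab)
  scores <- scores[keep]; lab <- lab[keep]
  if (length(unique(scores)) == 1 || length(unique(lab)) == 1)
    return(NA_real_)
  stats::cor(scores, lab, method = "spearman")
}
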