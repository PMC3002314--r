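#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around the standard rank-sum test with the convention used
#' throughout the pipeline: the exact null distribution when the smaller
#' group has at most 8 observations and there are no ties, and the
#' tie-corrected normal approximation (without continuity correction)
#' otherwise.
#'
#' @param x,y numeric vectors, each nonempty.
#' @return list with `statistic` (the rank-sum W for `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group in rank-sum test")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Differential expression between tumor and normal samples
#'
#' Per-feature Wilcoxon rank-sum tests with Bonferroni control: a feature is
#' significant when its p-value falls below `alpha` divided by the number of
#' features actually tested (zero-variance features are excluded and
#' reported).  Direction is called by comparing group medians (up =
#' tumor median above normal median); features with tied medians get an
#' `NA` direction.
#'
#' @param expr features x samples numeric matrix.
#' @param groups character vector over `colnames(expr)` (or same length as
#'   the columns) with values `"tumor"` / `"normal"`, each group of size
#'   `>= 2`.
#' @param alpha family-wise level, default 0.05.
#' @return data frame with columns `feature`, `p_value`, `significant`,
#'   `direction`, plus attributes `threshold`, `n_tested`, `excluded`.
#' @export
de_analysis <- function(expr, groups, alpha = 0.05) {
  expr <- as.matrix(expr)
  if (!is.null(names(groups))) groups <- groups[colnames(expr)]
  stopifnot(length(groups) == ncol(expr),
            all(groups %in% c("tumor", "normal")))
  tum <- groups == "tumor"; nor <- groups == "normal"
  if (sum(tum) < 2 || sum(nor) < 2)
    stop("each group needs at least 2 samples")
  rv <- apply(expr, 1, stats::var)
  excluded <- rownames(expr)[rv == 0]
  keep <- rv > 0
  m <- sum(keep)
  if (m == 0) stop("no nonconstant features to test")
  thr <- bonferroni_threshold(alpha, m)
  sub <- expr[keep, , drop = FALSE]
  p <- apply(sub, 1, function(z) wilcoxon_rank_sum(z[tum], z[nor])$p)
  med_t <- apply(sub[, tum, drop = FALSE], 1, stats::median)
  med_n <- apply(sub[, nor, drop = FALSE], 1, stats::median)
  direction <- ifelse(med_t > med_n, "up",
                      ifelse(med_t < med_n, "down", NA_character_))
  out <- data.frame(feature = rownames(sub), p_value = p,
                    significant = p < thr, direction = direction,
                    row.names = NULL)
  attr(out, "threshold") <- thr
  attr(out, "n_tested") <- m
  attr(out, "excluded") <- excluded
  out
}
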