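#' Per-test Bonferroni significance threshold
#'
#' The family-wise threshold used throughout the pipeline: `alpha / m`, where
#' `m` is the number of tests actually performed.  With the study's feature
#' counts this gives 4.15e-6 (12,042 mRNAs), 9.36e-5 (534 miRNAs), 1.63e-4
#' (306 somatic-mutation genes) and 4.03e-4 (124 LOH genes) at `alpha = 0.05`.
#'
#' @param alpha family-wise error level, in (0, 1).
#' @param m number of tests in the family, a positive integer.
#' @return the per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1)
  alpha / m
}

#' Univariate least-squares regression statistics
#'
#' Closed-form simple linear regression of `y` on `x`: slope, intercept,
#' two-sided t-test p-value for slope = 0, and the coefficient of
#' determination R-squared.  This is the workhorse behind both the
#' miRNA-target filter and the group eQTL scan.
#'
#' @param y numeric response vector.
#' @param x numeric predictor vector, same length as `y`, nonconstant.
#' @return a list with `slope`, `intercept`, `se`, `t`, `p`, `r_squared`,
#'   `n`.
#' @export
simple_regression <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3) stop("need at least 3 complete observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant predictor: regression undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  rss <- max(rss, 0)
  r2 <- if (syy > 0) 1 - rss / syy else NA_real_
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, se = se, t = tval,
       p = p, r_squared = r2, n = n)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  Generators take explicit seeds and must not
# clobber global randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stage label,
# so each stochastic stage of the pipeline consumes its own stream.  A
# polynomial rolling hash keeps distinct labels on distinct streams.
derive_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% m
  as.integer(h)
}
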