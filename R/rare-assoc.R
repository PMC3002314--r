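#' Group burden test statistic for rare mutation counts
#'
#' Compares mean per-sample mutation counts between tumor and normal groups:
#' `T = (Ubar - Vbar)^2 / ((1/n_A + 1/n_G) * S_uv)` where `S_uv` is the
#' pooled sample variance
#' `((n_A - 1) s_U^2 + (n_G - 1) s_V^2) / (n_A + n_G - 2)`.  `T` is the
#' square of the pooled two-sample t statistic and is asymptotically
#' chi-square with 1 degree of freedom under equal group intensities.  When
#' both groups are constant with equal means the statistic is degenerate and
#' reported as `T = 0` with a flag (conservative).
#'
#' @param u tumor-group count vector (length `n_A >= 2`).
#' @param v normal-group count vector (length `n_G >= 2`).
#' @return list with `statistic`, `s_uv` and `degenerate`.
#' @export
group_test_statistic <- function(u, v) {
  stopifnot(length(u) >= 2, length(v) >= 2)
  n_a <- length(u); n_g <- length(v)
  s_uv <- ((n_a - 1) * stats::var(u) + (n_g - 1) * stats::var(v)) /
    (n_a + n_g - 2)
  if (s_uv == 0) {
    # zero pooled variance forces both groups constant, hence equal means
    # whenever there is no signal; conservative T = 0
    return(list(statistic = 0, s_uv = 0, degenerate = TRUE))
  }
  t_stat <- (mean(u) - mean(v))^2 / ((1 / n_a + 1 / n_g) * s_uv)
  list(statistic = t_stat, s_uv = s_uv, degenerate = FALSE)
}

#' Upper-tail chi-square(1) p-value for the burden statistic
#'
#' @param t statistic value(s), `>= 0`.
#' @return p-value(s) in (0, 1].
#' @export
chi2_pvalue <- function(t) {
  if (any(t < 0)) stop("statistic must be nonnegative")
  stats::pchisq(t, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment over the supplied family.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Burden association test across all genes of a mutation dataset
#'
#' Applies [group_test_statistic()] gene by gene under the requested
#' counting mode, converts to chi-square(1) p-values, and adjusts by
#' Benjamini-Hochberg across the tested family.  Genes with zero events in
#' both groups carry no information and are excluded from both the result
#' table and the FDR family.  The mutation frequency column is the fraction
#' of tumor samples carrying at least one event.
#'
#' @param dataset a [mutation_dataset()].
#' @param mode `"T_G"` or `"T_a"`, see [collapse_counts()].
#' @return data frame with columns `gene`, `statistic`, `p_value`, `fdr`,
#'   `mutation_frequency`, `mode`, `degenerate`, sorted by p-value.
#' @export
test_all_genes <- function(dataset, mode = c("T_G", "T_a")) {
  mode <- match.arg(mode)
  counts <- collapse_counts(dataset, mode)
  any_event <- colSums(counts$tumor) + colSums(counts$normal) > 0
  genes <- dataset$gene_ids[any_event]
  if (!length(genes)) {
    return(data.frame(gene = character(), statistic = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      mutation_frequency = numeric(), mode = character(),
                      degenerate = logical()))
  }
  res <- lapply(genes, function(g)
    group_test_statistic(counts$tumor[, g], counts$normal[, g]))
  stat <- vapply(res, `[[`, numeric(1), "statistic")
  degen <- vapply(res, `[[`, logical(1), "degenerate")
  p <- chi2_pvalue(stat)
  freq <- colMeans(dataset$tumor_events[, genes, drop = FALSE] > 0)
  out <- data.frame(gene = genes, statistic = stat, p_value = p,
                    fdr = bh_fdr(p), mutation_frequency = freq,
                    mode = mode, degenerate = degen,
                    row.names = NULL)
  out[order(out$p_value, out$gene), , drop = FALSE]
}

#' Type-I error simulation for the burden statistics
#'
#' Monte Carlo estimate of the rejection rate of the genotype (`T_G`) and
#' allele (`T_a`) burden statistics under the null: both groups drawn from
#' the same Poisson intensity, with each event independently homozygous at
#' the configured probability.  For each replicate a single gene is
#' simulated and both statistics computed; the table reports the fraction of
#' chi-square(1) p-values below each nominal level.
#'
#' The inner loop is vectorized over replicates (one matrix per group); the
#' row-wise statistic is algebraically identical to
#' [group_test_statistic()], which the test suite cross-checks.
#'
#' @param n_per_group samples per group (scalar or vector of sizes).
#' @param alphas nominal levels.
#' @param n_reps replicates per sample size (`>= 1000` recommended).
#' @param intensity null Poisson intensity per sample.
#' @param p_hom homozygote probability per event.
#' @param seed integer seed.
#' @return data frame with columns `n_per_group`, `statistic`, `alpha`,
#'   `rejection_rate`, `n_reps`.
#' @export
type1_error_experiment <- function(n_per_group, alphas = c(0.001, 0.01, 0.05),
                                   n_reps = 5000, intensity = 0.05,
                                   p_hom = 0.01, seed = 1L) {
  stopifnot(n_reps >= 1, all(n_per_group >= 2), intensity >= 0)
  rows <- list()
  for (n in n_per_group) {
    sub <- derive_seed(seed, paste0("type1_", n))
    pvals <- with_seed(sub, {
      draw <- function() {
        ev <- matrix(stats::rpois(n_reps * n, intensity), n_reps, n)
        hom <- matrix(stats::rbinom(length(ev), as.vector(ev), p_hom),
                      n_reps, n)
        list(g = ev, a = ev + hom)
      }
      tum <- draw(); nor <- draw()
      tstat <- function(u, v) {
        mu <- rowMeans(u); mv <- rowMeans(v)
        vu <- (rowSums(u * u) - n * mu^2) / (n - 1)
        vv <- (rowSums(v * v) - n * mv^2) / (n - 1)
        s_uv <- ((n - 1) * vu + (n - 1) * vv) / (2 * n - 2)
        t <- (mu - mv)^2 / ((2 / n) * s_uv)
        t[s_uv == 0] <- 0
        t
      }
      list(T_G = chi2_pvalue(tstat(tum$g, nor$g)),
           T_a = chi2_pvalue(tstat(tum$a, nor$a)))
    })
    for (stat in names(pvals)) {
      for (a in alphas) {
        # reject at p <= alpha: identical to p < alpha except at the p = 1
        # atom of degenerate replicates, so alpha = 1 rejects everything
        rows[[length(rows) + 1L]] <- data.frame(
          n_per_group = n, statistic = stat, alpha = a,
          rejection_rate = mean(pvals[[stat]] <= a), n_reps = n_reps)
      }
    }
  }
  do.call(rbind, rows)
}
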