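#' Simulate rare mutation events under the Poisson burden model
#'
#' Rare-allele counts in large samples behave as a Poisson process whose
#' intensity is the local mutation rate, so the generator draws per-sample,
#' per-gene event counts directly from Poisson distributions: the normal
#' group at the null intensity, the tumor group at the null intensity plus
#' any gene-specific excess from `effect_map`.  Each event is independently
#' homozygous with probability `p_hom`, which is what separates the
#' genotype-level and allele-level burden statistics.
#'
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a [mutation_dataset()] with a `truth` attribute naming the genes
#'   with planted excess intensity.
#' @export
simulate_rare_variants <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  lam <- rep_len(config$null_intensity, config$n_genes)
  names(lam) <- genes
  excess <- rep(0, config$n_genes); names(excess) <- genes
  if (length(config$effect_map)) {
    unknown <- setdiff(names(config$effect_map), genes)
    if (length(unknown))
      stop("effect_map names not on the gene panel: ",
           paste(unknown, collapse = ", "))
    excess[names(config$effect_map)] <- config$effect_map
  }
  nA <- config$n_tumor; nG <- config$n_normal
  with_seed(seed, {
    tum <- matrix(stats::rpois(nA * config$n_genes,
                               rep(lam + excess, each = nA)),
                  nA, config$n_genes,
                  dimnames = list(sprintf("T%04d", seq_len(nA)), genes))
    nor <- matrix(stats::rpois(nG * config$n_genes,
                               rep(lam, each = nG)),
                  nG, config$n_genes,
                  dimnames = list(sprintf("N%04d", seq_len(nG)), genes))
    tum_hom <- matrix(stats::rbinom(length(tum), as.vector(tum),
                                    config$p_hom),
                      nA, config$n_genes, dimnames = dimnames(tum))
    nor_hom <- matrix(stats::rbinom(length(nor), as.vector(nor),
                                    config$p_hom),
                      nG, config$n_genes, dimnames = dimnames(nor))
    ds <- mutation_dataset(tum, nor, tum_hom, nor_hom)
    attr(ds, "truth") <- list(effect_genes = names(excess)[excess > 0],
                              null_intensity = lam, excess = excess)
    ds
  })
}

#' Draw expression data from a known Gaussian graphical model
#'
#' Samples zero-mean multivariate normal expression with the precision
#' matrix implied by a [ggm_spec()]; the nonzero off-diagonal precision
#' entries are the ground-truth conditional-dependence edges recorded for
#' network-recovery tests.
#'
#' @param config a [sim_config()] carrying `mrna_ggm` / `mirna_ggm`.
#' @param n_samples number of samples (columns) to draw.
#' @param kind `"mrna"` or `"mirna"`: which spec to use.
#' @param sample_ids optional column names.
#' @param seed optional integer overriding `config$seed`.
#' @return features x samples numeric matrix, with attributes `kind` and
#'   `truth` (the true edge data frame).
#' @export
simulate_expression_ggm <- function(config, n_samples,
                                    kind = c("mrna", "mirna"),
                                    sample_ids = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_samples >= 1)
  kind <- match.arg(kind)
  spec <- if (kind == "mrna") config$mrna_ggm else config$mirna_ggm
  if (is.null(spec)) stop("no ggm_spec of kind '", kind, "' in config")
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0("ggm_", kind))
  r <- chol(spec$omega)  # omega = r'r  =>  x = r^{-1} z  has cov omega^{-1}
  with_seed(seed, {
    z <- matrix(stats::rnorm(spec$q * n_samples), spec$q, n_samples)
    x <- backsolve(r, z)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
    dimnames(x) <- list(spec$features, sample_ids)
    attr(x, "kind") <- kind
    attr(x, "truth") <- data.frame(
      a = spec$features[spec$edges$i],
      b = spec$features[spec$edges$j],
      rho = spec$edges$rho)
    x
  })
}

#' Plant repressive miRNA-target effects into an mRNA matrix
#'
#' For every pair in `target_spec` the target mRNA is rewritten as
#' `baseline + effect * miRNA + noise`, where the baseline is the target's
#' original mean, the effect is negative by construction (miRNAs repress
#' their targets) and the noise is Gaussian with the configured standard
#' deviation.  The realized per-pair R-squared is recorded in the truth
#' attribute.
#'
#' @param config a [sim_config()] with a `target_spec`.
#' @param mrna features x samples mRNA matrix.
#' @param mirna features x samples miRNA matrix sharing `mrna`'s columns.
#' @param seed optional integer overriding the derived sub-seed.
#' @return the modified mRNA matrix with a `truth` attribute (data frame of
#'   planted pairs with their realized R-squared).
#' @export
simulate_mirna_regulation <- function(config, mrna, mirna, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$target_spec
  if (is.null(spec) || !nrow(spec)) return(mrna)
  stopifnot(identical(colnames(mrna), colnames(mirna)))
  missing_mi <- setdiff(spec$mirna, rownames(mirna))
  missing_m <- setdiff(spec$mrna, rownames(mrna))
  if (length(missing_mi) || length(missing_m))
    stop("target_spec names absent from matrices: ",
         paste(c(missing_mi, missing_m), collapse = ", "))
  if (is.null(seed)) seed <- derive_seed(config$seed, "mirna_targets")
  n <- ncol(mrna)
  with_seed(seed, {
    realized <- numeric(nrow(spec))
    for (k in seq_len(nrow(spec))) {
      mi <- mirna[spec$mirna[k], ]
      base <- mean(mrna[spec$mrna[k], ])
      eps <- stats::rnorm(n, 0, spec$noise_sd[k])
      y <- base + spec$effect[k] * mi + eps
      mrna[spec$mrna[k], ] <- y
      realized[k] <- simple_regression(y, mi)$r_squared
    }
    truth <- spec
    truth$realized_r2 <- realized
    attr(mrna, "truth") <- truth
    mrna
  })
}

#' Plant additive mutation-dosage eQTL effects into an expression matrix
#'
#' For every row of `eqtl_spec` the target feature's expression is shifted
#' by `effect` times the sample's mutated-allele count in the mutation gene,
#' for the samples shared between the mutation and expression datasets.
#'
#' @param config a [sim_config()] with an `eqtl_spec`.
#' @param muts a [mutation_dataset()].
#' @param expr features x samples matrix whose tumor columns use the same
#'   sample ids as `muts`.
#' @param mode counting mode for the allele dosage, see [collapse_counts()].
#' @return the shifted matrix with a `truth` attribute.
#' @export
simulate_eqtl_effects <- function(config, muts, expr, mode = "T_a") {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$eqtl_spec
  if (is.null(spec) || !nrow(spec)) return(expr)
  counts <- collapse_counts(muts, mode)$tumor
  shared <- intersect(colnames(expr), rownames(counts))
  if (!length(shared))
    stop("no samples shared between mutation and expression data")
  missing_g <- setdiff(spec$gene, colnames(counts))
  missing_t <- setdiff(spec$target, rownames(expr))
  if (length(missing_g) || length(missing_t))
    stop("eqtl_spec names not found: ",
         paste(c(missing_g, missing_t), collapse = ", "))
  for (k in seq_len(nrow(spec))) {
    dose <- counts[shared, spec$gene[k]]
    expr[spec$target[k], shared] <-
      expr[spec$target[k], shared] + spec$effect[k] * dose
  }
  attr(expr, "truth") <- spec
  expr
}

#' Simulate proportional-hazards survival times
#'
#' Event times are exponential with rate `baseline_hazard *
#' exp(covariates %*% log_hazard)`.  Censoring is independent exponential
#' with rate chosen so that, under the baseline hazard, the expected
#' censored fraction equals `censor_rate`; a rate of zero disables
#' censoring.
#'
#' @param config a [sim_config()] (its `survival_spec` is used).
#' @param covariates samples x covariates numeric matrix; column names must
#'   cover `names(survival_spec$log_hazard)`.
#' @param seed optional integer overriding the derived sub-seed.
#' @return data frame with `sample`, `time`, `event` (1 = death observed).
#' @export
simulate_survival <- function(config, covariates, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$survival_spec
  if (sp$baseline_hazard <= 0) stop("baseline hazard must be positive")
  covariates <- as.matrix(covariates)
  n <- nrow(covariates)
  beta <- sp$log_hazard
  lp <- rep(0, n)
  if (length(beta)) {
    stopifnot(all(names(beta) %in% colnames(covariates)))
    lp <- as.vector(covariates[, names(beta), drop = FALSE] %*% beta)
  }
  if (is.null(seed)) seed <- derive_seed(config$seed, "survival")
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = sp$baseline_hazard * exp(lp))
    if (sp$censor_rate > 0) {
      cens_rate <- sp$baseline_hazard * sp$censor_rate / (1 - sp$censor_rate)
      t_cens <- stats::rexp(n, rate = cens_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    ids <- rownames(covariates)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
    data.frame(sample = ids,
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  })
}
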