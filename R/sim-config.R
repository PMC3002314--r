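#' Sparse Gaussian graphical model specification
#'
#' Defines the ground-truth conditional-dependence structure used to draw
#' multivariate normal expression data.  The implied precision matrix has
#' unit diagonal and off-diagonal entries `-rho` for each listed pair, so
#' that `rho` is (approximately, exactly in the pairwise case) the partial
#' correlation of the pair given all other features.  The matrix must be
#' symmetric positive definite; a specification that fails the Cholesky
#' check is rejected.
#'
#' @param q number of features.
#' @param edges data frame with columns `i`, `j` (1-based feature indices,
#'   `i != j`) and `rho` (partial correlation, `|rho| < 1`).  May be empty
#'   for an independence model.
#' @param features optional character vector of feature names (length `q`).
#' @return an object of class `ggm_spec` with elements `q`, `edges`,
#'   `features`, `omega` (the precision matrix) and `sigma` (its inverse).
#' @export
ggm_spec <- function(q, edges = NULL, features = NULL) {
  stopifnot(is.numeric(q), length(q) == 1L, q >= 1, q == round(q))
  if (is.null(features)) features <- sprintf("F%03d", seq_len(q))
  stopifnot(length(features) == q, !anyDuplicated(features))
  if (is.null(edges)) {
    edges <- data.frame(i = integer(), j = integer(), rho = numeric())
  }
  edges <- as.data.frame(edges)
  stopifnot(all(c("i", "j", "rho") %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$i >= 1), all(edges$j >= 1),
              all(edges$i <= q), all(edges$j <= q),
              all(edges$i != edges$j), all(abs(edges$rho) < 1))
    # canonical order i < j, one entry per pair
    swap <- edges$i > edges$j
    tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
    if (anyDuplicated(edges[, c("i", "j")]))
      stop("duplicate pairs in ggm edge specification")
  }
  omega <- diag(q)
  for (k in seq_len(nrow(edges))) {
    omega[edges$i[k], edges$j[k]] <- -edges$rho[k]
    omega[edges$j[k], edges$i[k]] <- -edges$rho[k]
  }
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch))
    stop("ggm_spec implies a non-positive-definite precision matrix")
  structure(list(q = q, edges = edges, features = features,
                 omega = omega, sigma = chol2inv(ch)),
            class = "ggm_spec")
}

#' Simulation configuration for the synthetic multi-omic study
#'
#' Bundles every quantity the generators need, with defaults matching the
#' study conditions the pipeline emulates: 179 tumor/normal pairs sequenced
#' over a somatic-gene panel, a rare-mutation Poisson intensity of 0.05
#' events per sample per gene (carrier fractions of a few percent, the range
#' of the observed mutation frequencies), a small homozygote probability so
#' the genotype- and allele-count statistics differ, repressive
#' miRNA-target effects, additive per-allele eQTL effects, and exponential
#' proportional-hazards survival.
#'
#' @param n_tumor,n_normal samples per group (positive integers).
#' @param n_genes number of mutation genes on the panel.
#' @param null_intensity expected mutation events per sample per gene under
#'   the null; scalar or per-gene vector, all `>= 0`.
#' @param effect_map named numeric vector of tumor-only excess intensities
#'   (names are gene ids); empty for a null study.
#' @param p_hom probability that a mutation event is homozygous (counted
#'   twice by the allele statistic); default 0.01.
#' @param mrna_ggm,mirna_ggm [ggm_spec()] objects for the mRNA and miRNA
#'   coexpression ground truth.
#' @param target_spec data frame of planted repressive miRNA-target pairs:
#'   columns `mirna`, `mrna`, `effect` (< 0), `noise_sd` (> 0).
#' @param eqtl_spec data frame of planted per-allele expression effects:
#'   columns `gene`, `target`, `effect`.
#' @param survival_spec list with `baseline_hazard` (> 0), `log_hazard`
#'   (named numeric, per-covariate log hazard ratios) and `censor_rate`
#'   (in `[0, 1)`).
#' @param de_spec data frame of planted tumor-vs-normal expression shifts:
#'   columns `feature`, `kind` (`"mrna"`/`"mirna"`), `shift` (added to the
#'   tumor group, in standardized expression units).
#' @param study_sizes named list of expression/clinical sample counts; the
#'   defaults mirror the study the generator emulates (243/10 mRNA
#'   tumor/normal arrays, 240/10 miRNA arrays, survival over the miRNA
#'   tumor samples).
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 179, n_normal = 179, n_genes = 306,
                       null_intensity = 0.05, effect_map = numeric(),
                       p_hom = 0.01,
                       mrna_ggm = NULL, mirna_ggm = NULL,
                       target_spec = NULL, eqtl_spec = NULL,
                       survival_spec = list(baseline_hazard = 0.1,
                                            log_hazard = numeric(),
                                            censor_rate = 0.3),
                       de_spec = NULL,
                       study_sizes = list(mrna_tumor = 243, mrna_normal = 10,
                                          mirna_tumor = 240,
                                          mirna_normal = 10),
                       seed = 1L) {
  stopifnot(n_tumor >= 1, n_normal >= 1, n_genes >= 1)
  stopifnot(all(null_intensity >= 0))
  if (length(null_intensity) != 1L && length(null_intensity) != n_genes)
    stop("null_intensity must be scalar or one value per gene")
  if (length(effect_map)) {
    stopifnot(!is.null(names(effect_map)), all(effect_map >= 0))
  }
  stopifnot(p_hom >= 0, p_hom <= 1)
  if (!is.null(target_spec)) {
    target_spec <- as.data.frame(target_spec)
    stopifnot(all(c("mirna", "mrna", "effect", "noise_sd") %in%
                    names(target_spec)))
    if (any(target_spec$effect >= 0))
      stop("target_spec effects must be negative (targets are repressive)")
    stopifnot(all(target_spec$noise_sd >= 0))
  }
  if (!is.null(eqtl_spec)) {
    eqtl_spec <- as.data.frame(eqtl_spec)
    stopifnot(all(c("gene", "target", "effect") %in% names(eqtl_spec)))
  }
  stopifnot(is.list(survival_spec),
            survival_spec$baseline_hazard > 0,
            survival_spec$censor_rate >= 0, survival_spec$censor_rate < 1)
  if (!is.null(de_spec)) {
    de_spec <- as.data.frame(de_spec)
    stopifnot(all(c("feature", "kind", "shift") %in% names(de_spec)),
              all(de_spec$kind %in% c("mrna", "mirna")))
  }
  stopifnot(is.list(study_sizes),
            all(c("mrna_tumor", "mrna_normal", "mirna_tumor",
                  "mirna_normal") %in% names(study_sizes)))
  structure(list(n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 n_genes = as.integer(n_genes),
                 null_intensity = null_intensity,
                 effect_map = effect_map,
                 p_hom = p_hom,
                 mrna_ggm = mrna_ggm, mirna_ggm = mirna_ggm,
                 target_spec = target_spec, eqtl_spec = eqtl_spec,
                 survival_spec = survival_spec,
                 de_spec = de_spec, study_sizes = study_sizes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Repressive effect size achieving a target coefficient of determination
#'
#' Solves the variance decomposition `R^2 = b^2 v / (b^2 v + s^2)` for the
#' (negative) slope `b`, given the predictor variance `v` and noise standard
#' deviation `s`: planted miRNA-target pairs can then be generated at a
#' prescribed population R-squared.
#'
#' @param r2 target coefficient of determination, in (0, 1).
#' @param var_x predictor (miRNA expression) variance.
#' @param noise_sd residual standard deviation.
#' @return the negative slope.
#' @export
effect_for_r2 <- function(r2, var_x = 1, noise_sd = 1) {
  stopifnot(r2 > 0, r2 < 1, var_x > 0, noise_sd > 0)
  -sqrt(r2 / (1 - r2)) * noise_sd / sqrt(var_x)
}
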