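#' Group regression of expression on mutated-allele burden
#'
#' Univariate least squares of a feature's expression on the total
#' mutated-allele count of a gene across samples — the group analogue of a
#' single-variant eQTL regression, usable when individual variants are too
#' rare to test.  Requires at least two distinct count values; otherwise a
#' flagged no-test result is returned.
#'
#' @param expr numeric expression vector.
#' @param allele_counts nonnegative integer vector, same samples.
#' @return list with `coefficient`, `p`, `r_squared`, `n`, `tested`.
#' @export
eqtl_regression <- function(expr, allele_counts) {
  stopifnot(length(expr) == length(allele_counts),
            all(allele_counts >= 0),
            all(allele_counts == round(allele_counts)))
  if (length(unique(allele_counts)) < 2)
    return(list(coefficient = NA_real_, p = NA_real_,
                r_squared = NA_real_, n = length(expr), tested = FALSE))
  r <- simple_regression(expr, allele_counts)
  list(coefficient = r$slope, p = r$p, r_squared = r$r_squared,
       n = r$n, tested = TRUE)
}

#' Expression fold change between mutation carriers and non-carriers
#'
#' Ratio of the mean expression among carrier samples (at least one mutated
#' allele) to the mean among non-carriers.  Undefined (flagged, `NA`) when
#' either group is empty or the non-carrier mean is zero.
#'
#' @param expr numeric expression vector.
#' @param carrier logical vector, same samples.
#' @return list with `fold_change` and `defined`.
#' @export
fold_change <- function(expr, carrier) {
  stopifnot(length(expr) == length(carrier), is.logical(carrier))
  if (!any(carrier) || all(carrier))
    return(list(fold_change = NA_real_, defined = FALSE))
  denom <- mean(expr[!carrier])
  if (denom == 0)
    return(list(fold_change = NA_real_, defined = FALSE))
  list(fold_change = mean(expr[carrier]) / denom, defined = TRUE)
}

#' Scan mutation genes against expression targets for cis/trans eQTL
#'
#' For every (mutation gene, expression target) combination, regresses the
#' target's expression on the gene's mutated-allele count over the samples
#' shared between the datasets.  Trans associations are declared at the
#' Bonferroni threshold `alpha / m` where, following the study's convention,
#' `m` is the number of mutation genes tested (`correct_over = "genes"`;
#' `"pairs"` gives the conservative alternative of correcting over all
#' regressions).  Cis associations — identifier matches via `locality_map` —
#' are declared at the unadjusted `alpha`.
#'
#' @param muts a [mutation_dataset()] (typically restricted to
#'   disease-associated genes).
#' @param expr features x samples expression matrix whose tumor columns
#'   share sample ids with `muts`.
#' @param target_kind `"mRNA"` or `"miRNA"`, recorded in the output.
#' @param alpha family-wise level, default 0.05.
#' @param locality_map optional data frame with columns `gene`, `feature`
#'   defining cis identifier matches (a gene is always cis to the feature of
#'   the same name).
#' @param mode allele counting mode, see [collapse_counts()].
#' @param correct_over `"genes"` (study convention) or `"pairs"`.
#' @return data frame with columns `mutation_gene`, `target`, `target_kind`,
#'   `coefficient`, `p`, `r_squared`, `fold_change`, `locality`,
#'   `significant`; attribute `trans_threshold`.
#' @export
scan_eqtl <- function(muts, expr, target_kind = c("mRNA", "miRNA"),
                      alpha = 0.05, locality_map = NULL, mode = "T_a",
                      correct_over = c("genes", "pairs")) {
  target_kind <- match.arg(target_kind)
  correct_over <- match.arg(correct_over)
  counts <- collapse_counts(muts, mode)$tumor
  shared <- intersect(colnames(expr), rownames(counts))
  if (!length(shared))
    stop("no samples shared between mutation and expression data")
  genes <- muts$gene_ids
  feats <- rownames(expr)
  m <- if (correct_over == "genes") length(genes)
       else length(genes) * length(feats)
  thr <- bonferroni_threshold(alpha, m)
  cis_pairs <- paste(feats, feats)  # identifier match
  if (!is.null(locality_map)) {
    locality_map <- as.data.frame(locality_map)
    stopifnot(all(c("gene", "feature") %in% names(locality_map)))
    cis_pairs <- c(cis_pairs,
                   paste(locality_map$gene, locality_map$feature))
  }
  rows <- vector("list", length(genes) * length(feats))
  idx <- 0L
  for (g in genes) {
    dose <- counts[shared, g]
    carrier <- dose > 0
    for (f in feats) {
      idx <- idx + 1L
      e <- expr[f, shared]
      r <- eqtl_regression(e, dose)
      fc <- fold_change(e, carrier)
      loc <- if (paste(g, f) %in% cis_pairs) "cis" else "trans"
      sig <- if (!r$tested) FALSE
             else if (loc == "cis") r$p < alpha else r$p < thr
      rows[[idx]] <- data.frame(
        mutation_gene = g, target = f, target_kind = target_kind,
        coefficient = r$coefficient, p = r$p, r_squared = r$r_squared,
        fold_change = fc$fold_change, locality = loc, significant = sig)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "trans_threshold") <- thr
  attr(out, "n_shared_samples") <- length(shared)
  out
}

#' Detect triangle regulation cycles
#'
#' A triangle is a mutation gene `g`, an mRNA `m` and a miRNA `mi` such that
#' `g` is a significant eQTL for both `m` and `mi`, and `(mi, m)` is an
#' accepted repressive target pair.  Each emitted row carries the three
#' member statistics.
#'
#' @param mrna_eqtl,mirna_eqtl data frames from [scan_eqtl()] (mRNA and
#'   miRNA targets respectively).
#' @param targets data frame from [filter_targets()].
#' @return data frame with one row per triangle: `mutation_gene`, `mrna`,
#'   `mirna` and the coefficient/p/r-squared of each of the three edges.
#' @export
find_triangles <- function(mrna_eqtl, mirna_eqtl, targets) {
  empty <- data.frame(
    mutation_gene = character(), mrna = character(), mirna = character(),
    mut_mrna_coef = numeric(), mut_mrna_p = numeric(),
    mut_mrna_r2 = numeric(),
    mut_mirna_coef = numeric(), mut_mirna_p = numeric(),
    mut_mirna_r2 = numeric(),
    mirna_mrna_coef = numeric(), mirna_mrna_p = numeric(),
    mirna_mrna_r2 = numeric())
  gm <- mrna_eqtl[mrna_eqtl$significant, , drop = FALSE]
  gmi <- mirna_eqtl[mirna_eqtl$significant, , drop = FALSE]
  acc <- targets[targets$accepted, , drop = FALSE]
  if (!nrow(gm) || !nrow(gmi) || !nrow(acc)) return(empty)
  rows <- list()
  for (k in seq_len(nrow(acc))) {
    mi <- acc$mirna[k]; m <- acc$mrna[k]
    g1 <- gm[gm$target == m, , drop = FALSE]
    g2 <- gmi[gmi$target == mi, , drop = FALSE]
    both <- intersect(g1$mutation_gene, g2$mutation_gene)
    for (g in both) {
      a <- g1[g1$mutation_gene == g, ][1, ]
      b <- g2[g2$mutation_gene == g, ][1, ]
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_gene = g, mrna = m, mirna = mi,
        mut_mrna_coef = a$coefficient, mut_mrna_p = a$p,
        mut_mrna_r2 = a$r_squared,
        mut_mirna_coef = b$coefficient, mut_mirna_p = b$p,
        mut_mirna_r2 = b$r_squared,
        mirna_mrna_coef = acc$coefficient[k], mirna_mrna_p = acc$p[k],
        mirna_mrna_r2 = acc$r_squared[k])
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
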