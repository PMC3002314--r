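#' Generate a complete synthetic multi-omic study
#'
#' Runs every generator in dependency order and returns all pipeline inputs
#' with a machine-readable ground-truth ledger: mutation events, mRNA and
#' miRNA expression (with planted tumor-vs-normal shifts, repressive
#' miRNA-target effects and additive mutation-dosage eQTL effects), and a
#' survival table over the miRNA tumor samples.  Tumor sample ids are nested
#' across data types (`T0001`, `T0002`, ...), so the sample overlaps the
#' integrated analyses need arise naturally.
#'
#' @param config a [sim_config()] with `mrna_ggm` and `mirna_ggm` set.
#' @return a list of class `sim_study` with elements `muts`, `mrna`,
#'   `mirna`, `groups_mrna`, `groups_mirna`, `surv`, `truth`, `config`.
#' @export
sim_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$mrna_ggm) || is.null(config$mirna_ggm))
    stop("sim_study needs both mrna_ggm and mirna_ggm specifications")
  sz <- config$study_sizes
  truth <- list()

  muts <- simulate_rare_variants(config)
  truth$burden <- attr(muts, "truth")

  ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  mrna_ids <- c(ids("T", sz$mrna_tumor), ids("NE", sz$mrna_normal))
  mirna_ids <- c(ids("T", sz$mirna_tumor), ids("NE", sz$mirna_normal))
  mrna <- simulate_expression_ggm(config, length(mrna_ids), "mrna",
                                  sample_ids = mrna_ids)
  mirna <- simulate_expression_ggm(config, length(mirna_ids), "mirna",
                                   sample_ids = mirna_ids)
  truth$mrna_edges <- attr(mrna, "truth")
  truth$mirna_edges <- attr(mirna, "truth")
  groups_mrna <- stats::setNames(
    rep(c("tumor", "normal"), c(sz$mrna_tumor, sz$mrna_normal)), mrna_ids)
  groups_mirna <- stats::setNames(
    rep(c("tumor", "normal"), c(sz$mirna_tumor, sz$mirna_normal)), mirna_ids)

  # repressive miRNA -> mRNA effects over the shared samples
  if (!is.null(config$target_spec) && nrow(config$target_spec)) {
    shared <- intersect(colnames(mrna), colnames(mirna))
    sub <- simulate_mirna_regulation(config, mrna[, shared, drop = FALSE],
                                     mirna[, shared, drop = FALSE])
    mrna[, shared] <- sub
    truth$targets <- attr(sub, "truth")
  }

  # planted tumor-vs-normal differential expression (applied after the
  # target rewiring so regulated genes keep their group shift)
  if (!is.null(config$de_spec) && nrow(config$de_spec)) {
    for (k in seq_len(nrow(config$de_spec))) {
      f <- config$de_spec$feature[k]
      if (config$de_spec$kind[k] == "mrna") {
        stopifnot(f %in% rownames(mrna))
        mrna[f, groups_mrna == "tumor"] <-
          mrna[f, groups_mrna == "tumor"] + config$de_spec$shift[k]
      } else {
        stopifnot(f %in% rownames(mirna))
        mirna[f, groups_mirna == "tumor"] <-
          mirna[f, groups_mirna == "tumor"] + config$de_spec$shift[k]
      }
    }
    truth$de <- config$de_spec
  }

  # additive mutation-dosage effects over samples shared with mutation data
  if (!is.null(config$eqtl_spec) && nrow(config$eqtl_spec)) {
    espec <- config$eqtl_spec
    is_mirna <- espec$target %in% rownames(mirna)
    cfg_with <- function(spec) { config$eqtl_spec <- spec; config }
    if (any(!is_mirna))
      mrna <- simulate_eqtl_effects(cfg_with(espec[!is_mirna, ]), muts, mrna)
    if (any(is_mirna))
      mirna <- simulate_eqtl_effects(cfg_with(espec[is_mirna, ]), muts,
                                     mirna)
    truth$eqtl <- espec
  }

  surv_cov <- t(mirna[, groups_mirna == "tumor", drop = FALSE])
  surv <- simulate_survival(config, surv_cov)
  truth$survival <- config$survival_spec

  structure(list(muts = muts, mrna = mrna, mirna = mirna,
                 groups_mrna = groups_mrna, groups_mirna = groups_mirna,
                 surv = surv, truth = truth, config = config),
            class = "sim_study")
}

#' Write a synthetic study to disk as plain-text tables
#'
#' Writes the mutation table (long TSV: `sample_id`, `group`, `gene`,
#' `count`, `hom_count`), the two expression matrices (TSV, first column
#' `feature`), sample-group tables, the survival table, and the
#' ground-truth ledger as JSON.
#'
#' @param study a [sim_study()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_sim_data <- function(study, outdir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(x, name, row_col = NULL) {
    path <- file.path(outdir, name)
    if (!is.null(row_col)) {
      x <- data.frame(tmp = rownames(x), as.data.frame(x),
                      check.names = FALSE)
      names(x)[1] <- row_col
    }
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  long_counts <- function(m, hom, group) {
    data.frame(sample_id = rep(rownames(m), ncol(m)),
               group = group,
               gene = rep(colnames(m), each = nrow(m)),
               count = as.vector(m),
               hom_count = if (is.null(hom)) 0L else as.vector(hom))
  }
  mut_long <- rbind(
    long_counts(study$muts$tumor_events, study$muts$tumor_hom, "tumor"),
    long_counts(study$muts$normal_events, study$muts$normal_hom, "normal"))
  wr(mut_long[mut_long$count > 0, ], "mutations.tsv")
  wr(study$mrna, "mrna_expression.tsv", row_col = "feature")
  wr(study$mirna, "mirna_expression.tsv", row_col = "feature")
  wr(data.frame(sample_id = names(study$groups_mrna),
                group = study$groups_mrna), "mrna_groups.tsv")
  wr(data.frame(sample_id = names(study$groups_mirna),
                group = study$groups_mirna), "mirna_groups.tsv")
  wr(study$surv, "survival.tsv")
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(study$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  files <- c(files, truth_path)
  invisible(files)
}
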