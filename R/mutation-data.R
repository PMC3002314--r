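#' Mutation event dataset for tumor and matched-normal groups
#'
#' Container for per-sample, per-gene mutation event counts in two disjoint
#' sample groups, with an optional parallel record of how many of those
#' events are homozygous.  The genotype-level burden statistic counts every
#' mutated site once; the allele-level statistic counts homozygous events
#' twice (see [collapse_counts()]).
#'
#' @param tumor_events,normal_events nonnegative integer matrices,
#'   samples x genes, identical gene columns.
#' @param tumor_hom,normal_hom matrices of the same shapes counting the
#'   homozygous events among `*_events` (elementwise `<=` the event count);
#'   `NULL` means zygosity is unknown and all events are treated as
#'   heterozygous.
#' @return an object of class `mutation_dataset`.
#' @export
mutation_dataset <- function(tumor_events, normal_events,
                             tumor_hom = NULL, normal_hom = NULL) {
  tumor_events <- as.matrix(tumor_events)
  normal_events <- as.matrix(normal_events)
  chk <- function(m) {
    stopifnot(is.numeric(m), all(m >= 0), all(m == round(m)))
  }
  chk(tumor_events); chk(normal_events)
  if (ncol(tumor_events) != ncol(normal_events))
    stop("tumor and normal groups must share the same gene universe")
  genes <- colnames(tumor_events)
  if (is.null(genes)) {
    genes <- sprintf("G%04d", seq_len(ncol(tumor_events)))
    colnames(tumor_events) <- colnames(normal_events) <- genes
  }
  if (!identical(genes, colnames(normal_events)))
    stop("tumor and normal gene columns differ")
  common <- intersect(rownames(tumor_events), rownames(normal_events))
  if (length(common))
    stop("tumor and normal sample sets must be disjoint: ",
         paste(utils::head(common, 5), collapse = ", "))
  fix_hom <- function(hom, ev, label) {
    if (is.null(hom)) return(NULL)
    hom <- as.matrix(hom)
    chk(hom)
    stopifnot(identical(dim(hom), dim(ev)))
    if (any(hom > ev))
      stop("homozygous counts exceed event counts in ", label)
    dimnames(hom) <- dimnames(ev)
    hom
  }
  structure(list(tumor_events = tumor_events,
                 normal_events = normal_events,
                 tumor_hom = fix_hom(tumor_hom, tumor_events, "tumor"),
                 normal_hom = fix_hom(normal_hom, normal_events, "normal"),
                 gene_ids = genes),
            class = "mutation_dataset")
}

#' @export
print.mutation_dataset <- function(x, ...) {
  cat("mutation_dataset:", nrow(x$tumor_events), "tumor /",
      nrow(x$normal_events), "normal samples,",
      length(x$gene_ids), "genes,",
      if (is.null(x$tumor_hom)) "zygosity unknown" else "zygosity recorded",
      "\n")
  invisible(x)
}

#' Collapse mutation events to genotype- or allele-level counts
#'
#' Under the genotype statistic (`mode = "T_G"`) every mutated site
#' contributes one count; under the allele statistic (`mode = "T_a"`)
#' homozygous events are counted twice.  When the dataset carries no
#' zygosity information all events default to heterozygous, making the two
#' modes coincide.
#'
#' @param dataset a [mutation_dataset()].
#' @param mode `"T_G"` (genotype counts) or `"T_a"` (allele counts).
#' @return list with `tumor` and `normal` count matrices.
#' @export
collapse_counts <- function(dataset, mode = c("T_G", "T_a")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "mutation_dataset"))
  tum <- dataset$tumor_events
  nor <- dataset$normal_events
  if (mode == "T_a" && !is.null(dataset$tumor_hom)) {
    tum <- tum + dataset$tumor_hom
    nor <- nor + dataset$normal_hom
  }
  list(tumor = tum, normal = nor)
}

#' Encode loss-of-heterozygosity events from matched genotype tables
#'
#' An LOH event is recorded for a (sample, site) where the normal-tissue
#' genotype is heterozygous and the matched tumor-tissue genotype is
#' homozygous (either homozygous reference, the usual loss of the variant
#' chromosome, or homozygous alternate).  Events are summed over sites
#' within a gene.  A missing genotype in either member of the pair yields no
#' event.
#'
#' @param normal_genotypes,tumor_genotypes data frames with columns
#'   `sample`, `gene`, `site`, `genotype` where genotype is one of
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.  Every (sample, gene,
#'   site) row in one table must have a matching row in the other.
#' @return a [mutation_dataset()]-compatible sample x gene event-count
#'   matrix (all events heterozygous-equivalent: LOH is a genotype-level
#'   event).
#' @export
loh_encode <- function(normal_genotypes, tumor_genotypes) {
  req <- c("sample", "gene", "site", "genotype")
  normal_genotypes <- as.data.frame(normal_genotypes)
  tumor_genotypes <- as.data.frame(tumor_genotypes)
  stopifnot(all(req %in% names(normal_genotypes)),
            all(req %in% names(tumor_genotypes)))
  codes <- c("hom_ref", "het", "hom_alt", "missing")
  stopifnot(all(normal_genotypes$genotype %in% codes),
            all(tumor_genotypes$genotype %in% codes))
  key <- function(d) paste(d$sample, d$gene, d$site, sep = "\r")
  kn <- key(normal_genotypes); kt <- key(tumor_genotypes)
  bad <- c(setdiff(kn, kt), setdiff(kt, kn))
  if (length(bad))
    stop("unmatched sample/site pairs between normal and tumor tables: ",
         paste(gsub("\r", ":", utils::head(bad, 5)), collapse = ", "))
  ord <- match(kn, kt)
  event <- normal_genotypes$genotype == "het" &
    tumor_genotypes$genotype[ord] %in% c("hom_ref", "hom_alt")
  samples <- sort(unique(normal_genotypes$sample))
  genes <- sort(unique(normal_genotypes$gene))
  counts <- matrix(0L, length(samples), length(genes),
                   dimnames = list(samples, genes))
  if (any(event)) {
    tab <- table(normal_genotypes$sample[event], normal_genotypes$gene[event])
    counts[rownames(tab), colnames(tab)] <-
      counts[rownames(tab), colnames(tab)] + as.integer(tab)
  }
  counts
}
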