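#' Regress a target mRNA on a miRNA
#'
#' Ordinary least squares of the target's expression on the miRNA's
#' expression, reporting the slope, the two-sided t-test p-value for a zero
#' slope, and the coefficient of determination.  A candidate pair is
#' accepted as a genuine miRNA target only when the slope is negative
#' (miRNAs repress their targets) and the p-value clears the filter
#' threshold.
#'
#' @param mrna_expr numeric response vector (target mRNA across samples).
#' @param mirna_expr numeric predictor vector, same samples.
#' @return list with `coefficient`, `p`, `r_squared`, `n`.
#' @export
regress_pair <- function(mrna_expr, mirna_expr) {
  r <- simple_regression(mrna_expr, mirna_expr)
  list(coefficient = r$slope, p = r$p, r_squared = r$r_squared, n = r$n)
}

#' Filter candidate miRNA-target pairs by negative expression regression
#'
#' Sequence-based candidate pairs are retained only when the target's
#' expression shows a significant negative regression on the miRNA's
#' expression across the shared samples.  Pairs whose members are missing
#' from the matrices are skipped and reported via the `skipped` attribute.
#' The default threshold 1e-4 is applied without multiplicity correction.
#'
#' @param candidates data frame with columns `mirna`, `mrna` (additional
#'   columns are carried through).
#' @param mrna,mirna features x samples expression matrices sharing sample
#'   columns.
#' @param p_threshold significance threshold for the slope test.
#' @return data frame with columns `mirna`, `mrna`, `coefficient`, `p`,
#'   `r_squared`, `accepted`, plus a `skipped` attribute listing unusable
#'   candidate rows.
#' @export
filter_targets <- function(candidates, mrna, mirna, p_threshold = 1e-4) {
  candidates <- as.data.frame(candidates)
  if (!nrow(candidates)) {
    out <- data.frame(mirna = character(), mrna = character(),
                      coefficient = numeric(), p = numeric(),
                      r_squared = numeric(), accepted = logical())
    attr(out, "skipped") <- candidates
    return(out)
  }
  stopifnot(all(c("mirna", "mrna") %in% names(candidates)))
  shared <- intersect(colnames(mrna), colnames(mirna))
  if (length(shared) < 3)
    stop("fewer than 3 shared samples between the expression matrices")
  usable <- candidates$mirna %in% rownames(mirna) &
    candidates$mrna %in% rownames(mrna)
  skipped <- candidates[!usable, , drop = FALSE]
  cand <- candidates[usable, , drop = FALSE]
  res <- lapply(seq_len(nrow(cand)), function(k)
    regress_pair(mrna[cand$mrna[k], shared], mirna[cand$mirna[k], shared]))
  out <- data.frame(
    mirna = cand$mirna, mrna = cand$mrna,
    coefficient = vapply(res, `[[`, numeric(1), "coefficient"),
    p = vapply(res, `[[`, numeric(1), "p"),
    r_squared = vapply(res, `[[`, numeric(1), "r_squared"),
    row.names = NULL)
  out$accepted <- out$coefficient < 0 & out$p < p_threshold
  attr(out, "skipped") <- skipped
  out
}

#' Combined miRNA-target network
#'
#' Builds a mixed graph: directed arcs for every accepted miRNA-target pair,
#' plus the undirected coexpression edges of the two input networks
#' restricted to the nodes that appear in the combined graph.  Edges carry
#' an `arc` attribute distinguishing regulation arcs (`TRUE`) from
#' coexpression edges (`FALSE`).
#'
#' @param targets data frame from [filter_targets()] (only `accepted` rows
#'   are used).
#' @param mrna_net,mirna_net optional igraphs from [build_network()].
#' @return a directed igraph (coexpression edges appear as reciprocal
#'   `arc = FALSE` pairs is avoided: they are stored once with
#'   `arc = FALSE`).
#' @export
target_network <- function(targets, mrna_net = NULL, mirna_net = NULL) {
  acc <- targets[targets$accepted, , drop = FALSE]
  nodes <- unique(c(acc$mirna, acc$mrna))
  coex <- list()
  for (net in list(mrna_net, mirna_net)) {
    if (is.null(net)) next
    keep <- intersect(igraph::V(net)$name, nodes)
    sub <- igraph::induced_subgraph(net, keep)
    if (igraph::ecount(sub) > 0) {
      el <- igraph::as_data_frame(sub, what = "edges")
      coex[[length(coex) + 1L]] <- el[, c("from", "to")]
    }
    nodes <- unique(c(nodes, keep))
  }
  arcs <- data.frame(from = acc$mirna, to = acc$mrna,
                     arc = rep(TRUE, nrow(acc)))
  edges <- if (length(coex)) do.call(rbind, coex) else
    data.frame(from = character(), to = character())
  edges$arc <- rep(FALSE, nrow(edges))
  all_edges <- rbind(arcs, edges)
  igraph::graph_from_data_frame(
    all_edges, directed = TRUE,
    vertices = data.frame(name = nodes))
}
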