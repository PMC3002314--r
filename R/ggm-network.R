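#' Build a coexpression network from a lasso fit
#'
#' Creates an undirected igraph with one vertex per fitted feature and an
#' edge for every pair whose shared coefficient exceeds the numerical edge
#' tolerance in magnitude; edge `weight` and `theta` carry the coefficient.
#' When a differential-expression table is supplied its direction calls are
#' attached as a vertex attribute.
#'
#' @param fit a `ggm_fit` from [fit_joint_lasso()].
#' @param de_table optional data frame from [de_analysis()].
#' @param edge_tol magnitude below which a coefficient is numerical zero.
#' @return an igraph object.
#' @export
build_network <- function(fit, de_table = NULL, edge_tol = 1e-8) {
  stopifnot(inherits(fit, "ggm_fit"), edge_tol >= 0)
  keep <- abs(fit$theta) > edge_tol
  el <- cbind(fit$features[fit$pairs$i[keep]],
              fit$features[fit$pairs$j[keep]])
  gr <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2],
               weight = fit$theta[keep], theta = fit$theta[keep]),
    directed = FALSE,
    vertices = data.frame(name = fit$features))
  if (!is.null(de_table)) {
    idx <- match(fit$features, de_table$feature)
    gr <- igraph::set_vertex_attr(gr, "direction",
                                  value = de_table$direction[idx])
    gr <- igraph::set_vertex_attr(gr, "de_p", value = de_table$p_value[idx])
  }
  gr
}

#' Detect coexpression modules by adaptive dendrogram cutting
#'
#' Hierarchically clusters network nodes on the dissimilarity
#' `1 - |Pearson correlation|` (unsigned, so up- and down-regulated partners
#' share a module) with average linkage, then cuts the dendrogram at the
#' branch count maximizing the average silhouette width — the normalized
#' contrast between each node's within-branch and nearest-other-branch
#' dissimilarity, which is maximal when branches are tight and well
#' separated and degrades when coherent branches are fragmented.  A cut is
#' only accepted when the best silhouette exceeds `min_sil`; otherwise the
#' data are treated as unstructured and no modules are reported.  Accepted
#' branches smaller than `min_size` are left unassigned (module id 0);
#' modules are numbered by decreasing size.
#'
#' @param network an igraph from [build_network()] (its vertices name the
#'   features to cluster), or `NULL` to cluster all rows of `expr`.
#' @param expr features x samples expression matrix covering the nodes.
#' @param min_size smallest branch size that counts as a module.
#' @param min_sil minimum average silhouette width for a cut to be
#'   accepted; default 0.1.
#' @param max_k largest number of branches considered.
#' @return named integer vector: module id per node (0 = unassigned), with
#'   attribute `silhouette` (the achieved average silhouette width).
#' @export
detect_modules <- function(network, expr, min_size = 10, min_sil = 0.1,
                           max_k = 25) {
  nodes <- if (is.null(network)) rownames(expr) else igraph::V(network)$name
  missing <- setdiff(nodes, rownames(expr))
  if (length(missing))
    stop("nodes absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  q <- length(nodes)
  assign0 <- stats::setNames(rep(0L, q), nodes)
  if (q < 2 || q < min_size) {
    attr(assign0, "silhouette") <- 0
    return(assign0)
  }
  d <- 1 - abs(stats::cor(t(expr[nodes, , drop = FALSE])))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ks <- 2:min(max_k, q - 1)
  asw <- function(cl) {
    sizes <- table(cl)
    s <- numeric(q)
    for (i in seq_len(q)) {
      own <- cl[i]
      if (sizes[[as.character(own)]] == 1L) { s[i] <- 0; next }
      a <- sum(d[i, cl == own]) / (sizes[[as.character(own)]] - 1)
      b <- min(vapply(setdiff(names(sizes), as.character(own)),
                      function(g) mean(d[i, cl == as.integer(g)]),
                      numeric(1)))
      s[i] <- (b - a) / max(a, b)
    }
    mean(s)
  }
  scores <- vapply(ks, function(k) asw(stats::cutree(hc, k)), numeric(1))
  best <- which.max(scores)
  if (!length(scores) || scores[best] <= min_sil) {
    attr(assign0, "silhouette") <- if (length(scores)) scores[best] else 0
    return(assign0)
  }
  cl <- stats::cutree(hc, ks[best])
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  keep <- keep[order(-sizes[as.character(keep)])]
  out <- stats::setNames(rep(0L, q), nodes)
  for (m in seq_along(keep)) out[cl == keep[m]] <- m
  attr(out, "silhouette") <- scores[best]
  out
}

#' One-sided Fisher exact (hypergeometric) enrichment of modules
#'
#' For every module and gene set, tests whether the overlap between the
#' module and the set is larger than expected by chance within the feature
#' universe: the upper-tail hypergeometric probability of seeing at least
#' the observed overlap.  Sets with no member in the universe are skipped.
#'
#' @param modules named integer vector from [detect_modules()].
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all features eligible for membership;
#'   defaults to the names of `modules`.
#' @return data frame with `module`, `set`, `overlap`, `module_size`,
#'   `set_size`, `p_value`.
#' @export
fisher_enrichment <- function(modules, sets, universe = names(modules)) {
  stopifnot(!is.null(names(modules)), is.list(sets), !is.null(names(sets)))
  universe <- unique(universe)
  n_univ <- length(universe)
  mod_ids <- sort(unique(modules[modules > 0]))
  rows <- list()
  for (s in names(sets)) {
    set_u <- intersect(sets[[s]], universe)
    if (!length(set_u)) next
    for (m in mod_ids) {
      members <- intersect(names(modules)[modules == m], universe)
      k <- length(intersect(members, set_u))
      p <- stats::phyper(k - 1, length(set_u), n_univ - length(set_u),
                         length(members), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, overlap = k,
        module_size = length(members), set_size = length(set_u),
        p_value = p)
    }
  }
  if (!length(rows))
    return(data.frame(module = integer(), set = character(),
                      overlap = integer(), module_size = integer(),
                      set_size = integer(), p_value = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$p_value), , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
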