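#' Damage value of a network node
#'
#' Structural importance of a node `h`: with `V` the connected component
#' containing `h`, and `Vtilde` the largest connected component left after
#' deleting `h` from that component, the damage is `|V| - |Vtilde|`.  A node
#' whose removal keeps its component connected has damage 1 (itself); cut
#' vertices have larger damage.
#'
#' @param network an igraph object.
#' @param node vertex name.
#' @return list with `node`, `damage`, `component_size`.
#' @export
damage_value <- function(network, node) {
  if (!node %in% igraph::V(network)$name)
    stop("unknown node: ", node)
  comp <- igraph::components(network)
  cid <- comp$membership[node]
  members <- names(comp$membership)[comp$membership == cid]
  v_size <- length(members)
  if (v_size == 1L)
    return(list(node = node, damage = 1L, component_size = 1L))
  sub <- igraph::induced_subgraph(network, setdiff(members, node))
  v_tilde <- max(igraph::components(sub)$csize)
  list(node = node, damage = as.integer(v_size - v_tilde),
       component_size = v_size)
}

#' Rank nodes by damage value
#'
#' Computes [damage_value()] for each node of a subset and orders the
#' result by decreasing damage, breaking ties by node name for stable
#' output.
#'
#' @param network an igraph object.
#' @param nodes vertex names to rank; defaults to all vertices.
#' @return data frame with `node`, `damage`, `component_size`, sorted.
#' @export
rank_by_damage <- function(network, nodes = igraph::V(network)$name) {
  if (!length(nodes))
    return(data.frame(node = character(), damage = integer(),
                      component_size = integer()))
  rows <- lapply(nodes, function(h) {
    r <- damage_value(network, h)
    data.frame(node = r$node, damage = r$damage,
               component_size = r$component_size)
  })
  out <- do.call(rbind, rows)
  out[order(-out$damage, out$node), , drop = FALSE]
}

#' Topological summary of a network
#'
#' Largest-connected-component size, edge counts, and unweighted
#' shortest-path statistics (average over unordered reachable vertex pairs
#' of the largest component, and diameter) computed on the largest connected
#' component only.  An edgeless network has no defined path metrics and is
#' flagged.
#'
#' @param network an igraph object.
#' @return list with `n_nodes`, `n_edges`, `lcc_size`, `lcc_edges`,
#'   `average_shortest_path`, `diameter`, `degenerate`.
#' @export
network_summary <- function(network) {
  n_nodes <- igraph::vcount(network)
  n_edges <- igraph::ecount(network)
  if (n_edges == 0) {
    return(list(n_nodes = n_nodes, n_edges = 0L, lcc_size = NA_integer_,
                lcc_edges = NA_integer_, average_shortest_path = NA_real_,
                diameter = NA_real_, degenerate = TRUE))
  }
  comp <- igraph::components(network)
  lcc_id <- which.max(comp$csize)
  lcc <- igraph::induced_subgraph(
    network, names(comp$membership)[comp$membership == lcc_id])
  list(n_nodes = n_nodes, n_edges = n_edges,
       lcc_size = igraph::vcount(lcc),
       lcc_edges = igraph::ecount(lcc),
       average_shortest_path = igraph::mean_distance(lcc, weights = NA),
       diameter = igraph::diameter(lcc, weights = NA),
       degenerate = FALSE)
}
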