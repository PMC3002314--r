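# Independent oracles used across the suite.  Each recomputes a quantity by
# a route unrelated to the package implementation it checks.

# Brute-force damage value: recompute components from scratch with a BFS
# over an adjacency list, no igraph.
brute_damage <- function(edges, nodes, h) {
  adj <- lapply(stats::setNames(nm = nodes), function(x) character())
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp_of <- function(start, excluded = NULL) {
    seen <- character(); frontier <- start
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) {
        if (v %in% seen || v %in% excluded) next
        seen <- c(seen, v)
        nxt <- c(nxt, adj[[v]])
      }
      frontier <- setdiff(unique(nxt), c(seen, excluded))
    }
    seen
  }
  comp <- comp_of(h)
  rest <- setdiff(comp, h)
  if (!length(rest)) return(1L)
  sizes <- integer()
  while (length(rest)) {
    c1 <- comp_of(rest[1], excluded = h)
    sizes <- c(sizes, length(c1))
    rest <- setdiff(rest, c1)
  }
  length(comp) - max(sizes)
}

# Breslow log partial likelihood for a single covariate, evaluated
# directly from its definition (no survival package).
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (k in which(event == 1)) {
    risk <- time >= time[k]
    ll <- ll + beta * x[k] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Empirical partial correlation of features a and b given the rest, by
# inverting the empirical covariance matrix.
empirical_partial_cor <- function(x, a, b) {
  prec <- solve(stats::cov(t(x)))
  -prec[a, b] / sqrt(prec[a, a] * prec[b, b])
}

# Random small graph as an edge data frame over `n` named nodes.
random_graph_edges <- function(n, p_edge = 0.08) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  list(nodes = nodes,
       edges = data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                          stringsAsFactors = FALSE))
}

igraph_from_edges <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}
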