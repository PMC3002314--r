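#' Standardize an expression matrix feature-wise
#'
#' Centers each feature (row) to mean zero and scales to unit sample
#' standard deviation (denominator `n - 1`), the form the zero-mean Gaussian
#' graphical model assumes.  Constant features cannot be standardized and
#' are rejected by name.
#'
#' @param expr features x samples numeric matrix.
#' @return the standardized matrix (attributes preserved).
#' @export
standardize <- function(expr) {
  expr <- as.matrix(expr)
  if (any(!is.finite(expr))) stop("non-finite values in expression matrix")
  s <- apply(expr, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance feature(s): ",
         paste(utils::head(rownames(expr)[s == 0], 5), collapse = ", "))
  out <- (expr - rowMeans(expr)) / s
  dimnames(out) <- dimnames(expr)
  out
}

# Lexicographic (i < j) pair index table for q features.
pair_index <- function(q) {
  if (q < 2) return(data.frame(i = integer(), j = integer()))
  i <- rep(seq_len(q - 1), times = (q - 1):1)
  j <- unlist(lapply(seq_len(q - 1), function(a) (a + 1):q))
  data.frame(i = i, j = j)
}

#' Joint symmetric lasso objective for a Gaussian graphical model
#'
#' Direct evaluation of
#' `L(theta, lambda) = 1/2 sum_i ||Y_i - sum_{j != i} beta_ij Y_j||^2 +
#'  lambda sum_{i<j} |beta_ij|`
#' with the symmetry constraint `beta_ij = beta_ji = theta_(ij)`.  One
#' parameter is shared per unordered pair, so each `theta` appears in two of
#' the stacked regressions.  This evaluator computes the residuals
#' explicitly and is deliberately independent of the Gram-matrix shortcuts
#' used inside [fit_joint_lasso()].
#'
#' @param theta numeric vector of length `q(q-1)/2`, ordered
#'   lexicographically over pairs `(i < j)`.
#' @param expr standardized features x samples matrix (`q` rows).
#' @param lambda penalty `>= 0`.
#' @return the objective value.
#' @export
ggm_objective <- function(theta, expr, lambda) {
  expr <- as.matrix(expr)
  q <- nrow(expr)
  pairs <- pair_index(q)
  if (length(theta) != nrow(pairs))
    stop("theta must have length q(q-1)/2 = ", nrow(pairs))
  stopifnot(lambda >= 0)
  b <- matrix(0, q, q)
  b[cbind(pairs$i, pairs$j)] <- theta
  b[cbind(pairs$j, pairs$i)] <- theta
  rss <- 0
  for (i in seq_len(q)) {
    fit_i <- drop(b[i, , drop = FALSE] %*% expr)  # row i of B has 0 diagonal
    rss <- rss + sum((expr[i, ] - fit_i)^2)
  }
  rss / 2 + lambda * sum(abs(theta))
}

#' Fit the joint symmetric lasso by cyclic coordinate descent
#'
#' Minimizes the objective of [ggm_objective()] over the `q(q-1)/2` shared
#' pair parameters.  In the stacked formulation each pair `(i, j)` has
#' design column `X_(i,j)` placing `Y_j` in regression block `i` and `Y_i`
#' in block `j`, which enforces the symmetry `beta_ij = beta_ji`.  The
#' coordinate update is the exact one-dimensional minimizer, a soft
#' threshold:
#' `theta_j <- S(e'X_j / X_j'X_j + theta_j, lambda / X_j'X_j)`
#' with `X_j'X_j = ||Y_i||^2 + ||Y_j||^2` and `e` the current stacked
#' residual.  Parameters are initialized at the soft-thresholded marginal
#' solution `sign(Y'X_j)(|Y'X_j| - lambda)_+ / X_j'X_j` and updated in fixed
#' lexicographic order.  All inner products are carried on the q x q Gram
#' matrix, so a sweep costs `O(q^3)` independent of the sample count.
#'
#' @param expr standardized features x samples matrix.
#' @param lambda penalty `>= 0`.
#' @param tol convergence tolerance on the largest coordinate change per
#'   sweep.
#' @param max_iter maximum number of full sweeps.
#' @return an object of class `ggm_fit`: `theta` (named pair vector),
#'   `pairs`, `lambda`, `objective_trace` (objective after each sweep),
#'   `n_iter`, `converged`, `features`, `rss`, `n_samples`.
#' @export
fit_joint_lasso <- function(expr, lambda, tol = 1e-7, max_iter = 500) {
  expr <- as.matrix(expr)
  if (any(!is.finite(expr))) stop("non-finite values in expression matrix")
  stopifnot(lambda >= 0, tol > 0, max_iter >= 1)
  q <- nrow(expr)
  if (q < 2) stop("need at least two features")
  feats <- rownames(expr)
  if (is.null(feats)) feats <- sprintf("F%03d", seq_len(q))
  pairs <- pair_index(q)
  p <- nrow(pairs)
  g <- tcrossprod(expr)           # Gram matrix: g[i,j] = Y_i . Y_j
  denom <- diag(g)[pairs$i] + diag(g)[pairs$j]
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

  # initialization: soft-thresholded marginal solution per pair
  ytx <- 2 * g[cbind(pairs$i, pairs$j)]      # Y'X_(i,j) = 2 Y_i . Y_j
  theta <- soft(ytx, lambda) / denom

  bmat <- matrix(0, q, q)
  bmat[cbind(pairs$i, pairs$j)] <- theta
  bmat[cbind(pairs$j, pairs$i)] <- theta
  cmat <- bmat %*% g                          # (B G)[i,j] = fit_i . Y_j

  objective <- function() {
    rss <- sum(diag(g)) - 2 * sum(diag(cmat)) + sum(cmat * bmat)
    rss / 2 + lambda * sum(abs(theta))
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    max_delta <- 0
    for (k in seq_len(p)) {
      i <- pairs$i[k]; j <- pairs$j[k]
      # stacked residual inner product with X_(i,j), residual at current theta
      exj <- (g[i, j] - cmat[i, j]) + (g[j, i] - cmat[j, i])
      z <- exj / denom[k] + theta[k]
      new <- soft(z, lambda / denom[k])
      delta <- new - theta[k]
      if (delta != 0) {
        theta[k] <- new
        bmat[i, j] <- bmat[j, i] <- new
        cmat[i, ] <- cmat[i, ] + delta * g[j, ]
        cmat[j, ] <- cmat[j, ] + delta * g[i, ]
        max_delta <- max(max_delta, abs(delta))
      }
    }
    trace <- c(trace, objective())
    if (max_delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  rss_by_node <- pmax(diag(g) - 2 * diag(cmat) + rowSums(cmat * bmat), 0)
  names(theta) <- paste(feats[pairs$i], feats[pairs$j], sep = "|")
  structure(list(theta = theta, pairs = pairs, lambda = lambda,
                 objective_trace = trace, n_iter = iter,
                 converged = converged, features = feats,
                 rss = sum(rss_by_node), rss_by_node = rss_by_node,
                 n_samples = ncol(expr)),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat("ggm_fit:", length(x$features), "features,",
      sum(x$theta != 0), "nonzero pair coefficients, lambda =", x$lambda,
      if (x$converged) "(converged" else "(NOT converged",
      "in", x$n_iter, "sweeps)\n")
  invisible(x)
}

#' Select the lasso penalty over a grid
#'
#' `criterion = "bic"` minimizes an extended BIC over the grid: the sum of
#' per-node regression terms `n log(RSS_i / n)` plus the degrees-of-freedom
#' penalty `2 k log(n) + 4 gamma k log(q)`, where `k` is the number of
#' nonzero pair parameters (each shared between two of the `q` node
#' regressions, hence the factor 2) and the `gamma` term is the standard
#' graph-dimensionality correction for edge selection when the number of
#' candidate pairs is large relative to `n`; `gamma = 1` by default.
#' `criterion = "fixed"` passes the single grid value through.  The default
#' grid is 20 log-spaced values from the smallest penalty that zeroes every
#' coefficient (`max_j |Y'X_j|`) down by two decades.
#'
#' @param expr standardized features x samples matrix.
#' @param grid numeric penalty grid; `NULL` for the default.
#' @param criterion `"bic"` or `"fixed"`.
#' @param gamma extended-BIC graph-dimensionality weight in `[0, 1]`.
#' @param ... passed to [fit_joint_lasso()].
#' @return list with `lambda` (selected value), `table` (per-grid-point
#'   RSS, nonzero count and BIC) and `fit` (the fit at the selection).
#' @export
select_lambda <- function(expr, grid = NULL, criterion = c("bic", "fixed"),
                          gamma = 1, ...) {
  criterion <- match.arg(criterion)
  expr <- as.matrix(expr)
  if (criterion == "fixed") {
    if (is.null(grid) || length(grid) != 1L)
      stop("criterion = 'fixed' requires a single-value grid")
    return(list(lambda = grid, table = NULL,
                fit = fit_joint_lasso(expr, grid, ...)))
  }
  if (is.null(grid)) {
    g <- tcrossprod(expr)
    lmax <- max(abs(2 * g[upper.tri(g)]))
    grid <- exp(seq(log(lmax), log(lmax / 100), length.out = 20))
  }
  if (!length(grid)) stop("empty penalty grid")
  n <- ncol(expr)
  q <- nrow(expr)
  fits <- vector("list", length(grid))
  tab <- data.frame(lambda = grid, rss = NA_real_, nonzero = NA_integer_,
                    bic = NA_real_)
  for (k in seq_along(grid)) {
    fits[[k]] <- fit_joint_lasso(expr, grid[k], ...)
    tab$rss[k] <- fits[[k]]$rss
    tab$nonzero[k] <- sum(fits[[k]]$theta != 0)
    tab$bic[k] <- sum(n * log(pmax(fits[[k]]$rss_by_node, 1e-300) / n)) +
      2 * log(n) * tab$nonzero[k] +
      4 * gamma * log(q) * tab$nonzero[k]
  }
  best <- which.min(tab$bic)
  list(lambda = grid[best], table = tab, fit = fits[[best]])
}
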