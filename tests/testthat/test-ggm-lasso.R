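test_that("standardization centers and scales features", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  s <- standardize(x)
  expect_equal(unname(s["a", ]), c(-1, 0, 1))
  expect_equal(unname(s["b", ]), c(-1, 0, 1))
  expect_equal(standardize(s), s, tolerance = 1e-12)
  expect_error(standardize(rbind(x, flat = c(1, 1, 1))), "flat")
})

test_that("objective evaluator matches hand arithmetic", {
  # q = 2, n = 3 hand case: one shared parameter t
  y1 <- c(1, 0, -1); y2 <- c(2, 1, -3)
  x <- rbind(y1, y2)
  t0 <- 0.3; lam <- 0.7
  by_hand <- 0.5 * (sum((y1 - t0 * y2)^2) + sum((y2 - t0 * y1)^2)) +
    lam * abs(t0)
  expect_equal(ggm_objective(t0, x, lam), by_hand, tolerance = 1e-10)
  # zero theta: half the total sum of squares
  expect_equal(ggm_objective(0, x, 1), 0.5 * (sum(y1^2) + sum(y2^2)))
  # penalty nonnegativity
  expect_lte(ggm_objective(t0, x, 0), ggm_objective(t0, x, 2))
  expect_error(ggm_objective(c(1, 2), x, 1), "length")
})

test_that("coordinate descent solves the penalized problem", {
  set.seed(31)
  n <- 50
  spec <- ggm_spec(3, data.frame(i = c(1, 2), j = c(2, 3),
                                 rho = c(0.5, 0.4)))
  x <- standardize(simulate_expression_ggm(
    sim_config(mrna_ggm = spec, seed = 31), n, "mrna"))

  # kill condition: penalty above max |Y'X_j| zeroes every coefficient
  g <- tcrossprod(x)
  lmax <- max(abs(2 * g[upper.tri(g)]))
  fit0 <- fit_joint_lasso(x, lmax * 1.001)
  expect_true(all(fit0$theta == 0))
  # and the all-zero solution beats any perturbation under that penalty
  expect_lt(ggm_objective(fit0$theta, x, lmax * 1.001),
            ggm_objective(fit0$theta + 0.01, x, lmax * 1.001))

  # lambda = 0, q = 2: closed-form stacked least squares 2G12/(G11+G22)
  x2 <- x[1:2, , drop = FALSE]
  g2 <- tcrossprod(x2)
  fit2 <- fit_joint_lasso(x2, 0)
  expect_equal(unname(fit2$theta), 2 * g2[1, 2] / (g2[1, 1] + g2[2, 2]),
               tolerance = 1e-8)

  # objective trace nonincreasing and consistent with the direct evaluator
  fit <- fit_joint_lasso(x, 5)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_equal(utils::tail(fit$objective_trace, 1),
               ggm_objective(fit$theta, x, 5), tolerance = 1e-8)
  expect_true(fit$converged)

  # perturbing the solution never lowers the objective (optimality spot check)
  obj <- ggm_objective(fit$theta, x, 5)
  set.seed(1)
  for (k in 1:20) {
    pert <- fit$theta + stats::rnorm(length(fit$theta), 0, 0.01)
    expect_gte(ggm_objective(pert, x, 5), obj - 1e-8)
  }
  expect_error(fit_joint_lasso(x * NA, 1), "non-finite")
})

test_that("independent convex solver agrees on small instances", {
  skip_if_not_installed("glmnet")
  set.seed(37)
  for (k in 1:5) {
    q <- sample(3:4, 1); n <- 40
    x <- standardize(matrix(stats::rnorm(q * n), q, n))
    lam <- stats::runif(1, 0.5, 10)
    fit <- fit_joint_lasso(x, lam, tol = 1e-10)
    pairs <- fit$pairs
    N <- n * q
    xs <- matrix(0, N, nrow(pairs))
    yv <- numeric(N)
    for (i in 1:q) yv[((i - 1) * n + 1):(i * n)] <- x[i, ]
    for (j in seq_len(nrow(pairs))) {
      a <- pairs$i[j]; b <- pairs$j[j]
      xs[((a - 1) * n + 1):(a * n), j] <- x[b, ]
      xs[((b - 1) * n + 1):(b * n), j] <- x[a, ]
    }
    or <- glmnet::glmnet(xs, yv, lambda = lam / N, standardize = FALSE,
                         intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(as.vector(or$beta) - fit$theta)), 1e-4)
  }
})

test_that("BIC penalty selection recovers supports", {
  # one-point grid passes through
  set.seed(41)
  x <- standardize(matrix(stats::rnorm(5 * 60), 5, 60))
  one <- select_lambda(x, grid = 3, criterion = "fixed")
  expect_equal(one$lambda, 3)
  expect_error(select_lambda(x, grid = numeric(), criterion = "bic"),
               "empty")

  # independent features: few false edges at the selected penalty
  false_ok <- vapply(1:20, function(s) {
    xi <- standardize(simulate_expression_ggm(
      sim_config(mrna_ggm = ggm_spec(10), seed = 100 + s), 200, "mrna"))
    sum(select_lambda(xi)$fit$theta != 0) <= 1
  }, logical(1))
  expect_gte(mean(false_ok), 0.9)

  # strong chain: all true edges recovered at the selected penalty
  spec <- ggm_spec(10, data.frame(i = 1:9, j = 2:10, rho = 0.45))
  truth <- paste(spec$edges$i, spec$edges$j)
  got_all <- vapply(1:20, function(s) {
    xc <- standardize(simulate_expression_ggm(
      sim_config(mrna_ggm = spec, seed = 200 + s), 300, "mrna"))
    f <- select_lambda(xc)$fit
    got <- paste(f$pairs$i, f$pairs$j)[f$theta != 0]
    all(truth %in% got)
  }, logical(1))
  expect_gte(mean(got_all), 0.9)
})
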