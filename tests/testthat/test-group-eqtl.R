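test_that("eqtl regression and fold change match hand arithmetic", {
  r <- eqtl_regression(c(1, 1, 2, 3), c(0, 0, 1, 2))
  expect_equal(r$coefficient, 1)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_true(r$tested)

  # constant counts: flagged, not an error
  r0 <- eqtl_regression(c(1, 2, 3), c(1, 1, 1))
  expect_false(r0$tested)
  expect_true(is.na(r0$p))
  expect_error(eqtl_regression(c(1, 2), c(0, -1)))

  # on 0/1 counts the slope t-statistic is the two-sample pooled t
  set.seed(67)
  for (k in 1:30) {
    n <- 40
    cnt <- stats::rbinom(n, 1, 0.3)
    if (length(unique(cnt)) < 2) next
    y <- stats::rnorm(n) + cnt
    r <- simple_regression(y, cnt)
    tt <- stats::t.test(y[cnt == 1], y[cnt == 0], var.equal = TRUE)
    expect_equal(r$t^2, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  }

  expect_equal(fold_change(c(4, 4, 2, 2), c(TRUE, TRUE, FALSE, FALSE))$fold_change, 2)
  expect_equal(fold_change(c(1, 1, 2, 2), c(TRUE, TRUE, FALSE, FALSE))$fold_change, 0.5)
  expect_equal(fold_change(c(3, 3, 3, 3), c(TRUE, FALSE, TRUE, FALSE))$fold_change, 1)
  expect_false(fold_change(c(1, 2), c(FALSE, FALSE))$defined)
})

test_that("eqtl scan applies the gene-family Bonferroni convention", {
  set.seed(71)
  n <- 60
  sam <- sprintf("T%03d", 1:n)
  tum <- matrix(stats::rpois(n * 3, 0.5), n, 3,
                dimnames = list(sam, c("TP53", "EGFR", "RB1")))
  nor <- matrix(stats::rpois(n * 3, 0.5), n, 3,
                dimnames = list(sprintf("N%03d", 1:n), colnames(tum)))
  muts <- mutation_dataset(tum, nor)
  expr <- matrix(stats::rnorm(2 * n), 2, n,
                 dimnames = list(c("TP53", "GENEX"), sam))
  # plant a strong trans effect TP53 -> GENEX
  expr["GENEX", ] <- expr["GENEX", ] + 1.5 * tum[, "TP53"]
  sc <- scan_eqtl(muts, expr, "mRNA", alpha = 0.05)
  expect_equal(attr(sc, "trans_threshold"), 0.05 / 3)
  # identifier match makes TP53 -> TP53 cis
  expect_equal(sc$locality[sc$mutation_gene == "TP53" & sc$target == "TP53"],
               "cis")
  expect_equal(sc$locality[sc$mutation_gene == "TP53" & sc$target == "GENEX"],
               "trans")
  expect_true(sc$significant[sc$mutation_gene == "TP53" &
                               sc$target == "GENEX"])
  # correcting over pairs is more conservative
  sc_p <- scan_eqtl(muts, expr, "mRNA", alpha = 0.05,
                    correct_over = "pairs")
  expect_lt(attr(sc_p, "trans_threshold"), attr(sc, "trans_threshold"))
  # locality map extends cis matches
  sc_m <- scan_eqtl(muts, expr, "mRNA", alpha = 0.05,
                    locality_map = data.frame(gene = "EGFR",
                                              feature = "GENEX"))
  expect_equal(sc_m$locality[sc_m$mutation_gene == "EGFR" &
                               sc_m$target == "GENEX"], "cis")
  expect_error(scan_eqtl(muts, expr[, 1:0], "mRNA"), "shared")
})

test_that("triangle detection requires all three significant edges", {
  eq_m <- data.frame(mutation_gene = "RB1", target = "LAMP2",
                     target_kind = "mRNA", coefficient = 1.03,
                     p = 7e-4, r_squared = 0.065, fold_change = 1.2,
                     locality = "trans", significant = TRUE)
  eq_mi <- data.frame(mutation_gene = "RB1", target = "mir-340",
                      target_kind = "miRNA", coefficient = 1.81,
                      p = 4e-9, r_squared = 0.185, fold_change = 1.1,
                      locality = "trans", significant = TRUE)
  tg <- data.frame(mirna = "mir-340", mrna = "LAMP2",
                   coefficient = -277, p = 3e-6, r_squared = 0.085,
                   accepted = TRUE)
  tri <- find_triangles(eq_m, eq_mi, tg)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$mutation_gene, "RB1")
  expect_equal(tri$mirna_mrna_coef, -277)

  # dropping any edge removes the triangle
  expect_equal(nrow(find_triangles(eq_m[0, ], eq_mi, tg)), 0)
  eq_mi2 <- eq_mi; eq_mi2$significant <- FALSE
  expect_equal(nrow(find_triangles(eq_m, eq_mi2, tg)), 0)
  tg2 <- tg; tg2$accepted <- FALSE
  expect_equal(nrow(find_triangles(eq_m, eq_mi, tg2)), 0)
  # empty inputs: empty list
  expect_equal(nrow(find_triangles(eq_m[0, ], eq_mi[0, ], tg[0, ])), 0)
})
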