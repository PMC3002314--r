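test_that("group burden statistic matches hand arithmetic and the pooled t", {
  # hand-computed instance
  r <- group_test_statistic(c(2, 0, 1, 1), c(0, 1, 0, 0))
  expect_equal(r$s_uv, 0.4583333, tolerance = 1e-6)
  expect_equal(r$statistic, 2.454545, tolerance = 1e-6)
  expect_false(r$degenerate)

  # equal vectors: zero statistic
  expect_equal(group_test_statistic(c(1, 2, 3), c(1, 2, 3))$statistic, 0)

  # scale equivariance: doubling both groups leaves T unchanged
  expect_equal(group_test_statistic(2 * c(2, 0, 1, 1),
                                    2 * c(0, 1, 0, 0))$statistic,
               r$statistic, tolerance = 1e-12)

  # symmetry in group labels
  expect_equal(group_test_statistic(c(0, 1, 0, 0), c(2, 0, 1, 1))$statistic,
               r$statistic, tolerance = 1e-12)

  # degenerate: both groups constant
  d <- group_test_statistic(c(1, 1), c(1, 1))
  expect_true(d$degenerate)
  expect_equal(d$statistic, 0)

  # T equals the squared pooled-variance two-sample t on random instances
  set.seed(99)
  for (k in 1:100) {
    u <- stats::rpois(sample(5:40, 1), 0.5)
    v <- stats::rpois(sample(5:40, 1), 0.5)
    if (stats::var(u) + stats::var(v) == 0) next
    tt <- stats::t.test(u, v, var.equal = TRUE)
    expect_equal(group_test_statistic(u, v)$statistic,
                 unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("chi-square p-values and BH adjustment behave as specified", {
  expect_equal(chi2_pvalue(0), 1)
  expect_equal(chi2_pvalue(3.841459), 0.05, tolerance = 1e-4)
  expect_equal(chi2_pvalue(6.634897), 0.01, tolerance = 1e-4)
  expect_error(chi2_pvalue(-1), "nonnegative")

  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  # BH is monotone nondecreasing in sorted p order
  set.seed(4)
  p <- sort(stats::runif(50))
  expect_true(all(diff(bh_fdr(p)) >= -1e-12))
})

test_that("collapse_counts counts homozygous events twice only under T_a", {
  tum <- matrix(c(1L, 0L), 1, 2, dimnames = list("T1", c("g1", "g2")))
  nor <- matrix(0L, 1, 2, dimnames = list("N1", c("g1", "g2")))
  hom_t <- matrix(c(1L, 0L), 1, 2)
  hom_n <- matrix(0L, 1, 2)
  ds <- mutation_dataset(tum, nor, hom_t, hom_n)
  expect_equal(collapse_counts(ds, "T_G")$tumor[1, "g1"], 1)
  expect_equal(collapse_counts(ds, "T_a")$tumor[1, "g1"], 2)

  # het event counts once under both modes
  ds_het <- mutation_dataset(tum, nor, 0 * hom_t, hom_n)
  expect_equal(collapse_counts(ds_het, "T_a")$tumor[1, "g1"], 1)

  # no zygosity: T_a falls back to genotype counts
  ds_nz <- mutation_dataset(tum, nor)
  expect_identical(collapse_counts(ds_nz, "T_a"), collapse_counts(ds_nz, "T_G"))

  # empty dataset: all-zero matrices
  ds0 <- mutation_dataset(matrix(0L, 2, 2, dimnames = list(c("T1", "T2"), NULL)),
                          matrix(0L, 2, 2, dimnames = list(c("N1", "N2"), NULL)))
  expect_true(all(collapse_counts(ds0, "T_G")$tumor == 0))
})

test_that("loh_encode records het-to-hom transitions aggregated over sites", {
  nor <- data.frame(sample = c("s1", "s1", "s1", "s2"),
                    gene = c("gA", "gA", "gB", "gA"),
                    site = c(1, 2, 1, 1),
                    genotype = c("het", "het", "hom_ref", "het"))
  tum <- data.frame(sample = c("s1", "s1", "s1", "s2"),
                    gene = c("gA", "gA", "gB", "gA"),
                    site = c(1, 2, 1, 1),
                    genotype = c("hom_ref", "hom_alt", "hom_ref", "missing"))
  counts <- loh_encode(nor, tum)
  expect_equal(counts["s1", "gA"], 2)  # both het sites became hom
  expect_equal(counts["s1", "gB"], 0)  # was not heterozygous
  expect_equal(counts["s2", "gA"], 0)  # missing tumor genotype: no event

  # unmatched pairing is an error naming the offender
  expect_error(loh_encode(nor, tum[-1, ]), "unmatched")
})

test_that("per-gene association table excludes event-free genes and is calibrated", {
  # mutation frequency from a constructed dataset: 26 of 179 tumor samples
  tum <- matrix(0L, 179, 1, dimnames = list(sprintf("T%03d", 1:179), "TP53"))
  tum[1:26, 1] <- 1L
  nor <- matrix(0L, 179, 1, dimnames = list(sprintf("N%03d", 1:179), "TP53"))
  nor[1, 1] <- 1L
  tab <- test_all_genes(mutation_dataset(tum, nor), "T_G")
  expect_equal(tab$mutation_frequency, 26 / 179)
  expect_equal(round(tab$mutation_frequency, 4), 0.1453)

  # a gene with zero events everywhere is absent from the table
  tum2 <- cbind(tum, none = 0L); nor2 <- cbind(nor, none = 0L)
  tab2 <- test_all_genes(mutation_dataset(tum2, nor2), "T_G")
  expect_false("none" %in% tab2$gene)

  # level under the null: fraction of p < 0.05 near 0.05 across 306 genes
  cfg <- sim_config(n_tumor = 500, n_normal = 500, n_genes = 306,
                    null_intensity = 0.05, seed = 77)
  ds <- simulate_rare_variants(cfg)
  tabn <- test_all_genes(ds, "T_a")
  rate <- mean(tabn$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(tabn)))
  # fdr column respects BH ordering
  expect_true(all(tabn$fdr >= tabn$p_value - 1e-12))
})

test_that("vectorized type-I harness agrees with the per-gene statistic", {
  # alpha = 1 rejects everything
  tab1 <- type1_error_experiment(50, alphas = 1, n_reps = 50, seed = 2)
  expect_true(all(tab1$rejection_rate == 1))

  # the matrix fast path reproduces group_test_statistic p-values:
  # regenerate one replicate stream and compare rejection decisions
  n <- 200; reps <- 400
  tab <- type1_error_experiment(n, alphas = 0.05, n_reps = reps,
                                intensity = 0.05, p_hom = 0.01, seed = 9)
  slow <- with(new.env(), {
    sub <- gbmnet:::derive_seed(9, paste0("type1_", n))
    set.seed(sub)
    ev_t <- matrix(stats::rpois(reps * n, 0.05), reps, n)
    hom_t <- matrix(stats::rbinom(length(ev_t), as.vector(ev_t), 0.01),
                    reps, n)
    ev_n <- matrix(stats::rpois(reps * n, 0.05), reps, n)
    hom_n <- matrix(stats::rbinom(length(ev_n), as.vector(ev_n), 0.01),
                    reps, n)
    pg <- vapply(seq_len(reps), function(r)
      chi2_pvalue(group_test_statistic(ev_t[r, ], ev_n[r, ])$statistic),
      numeric(1))
    pa <- vapply(seq_len(reps), function(r)
      chi2_pvalue(group_test_statistic(ev_t[r, ] + hom_t[r, ],
                                       ev_n[r, ] + hom_n[r, ])$statistic),
      numeric(1))
    c(T_G = mean(pg < 0.05), T_a = mean(pa < 0.05))
  })
  expect_equal(tab$rejection_rate[tab$statistic == "T_G"],
               unname(slow["T_G"]))
  expect_equal(tab$rejection_rate[tab$statistic == "T_a"],
               unname(slow["T_a"]))
})
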