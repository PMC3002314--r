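test_that("rare-variant generator matches Poisson moments and ground truth", {
  # zero intensity: nothing mutates
  cfg0 <- sim_config(n_tumor = 20, n_normal = 20, n_genes = 5,
                     null_intensity = 0, seed = 3)
  ds0 <- simulate_rare_variants(cfg0)
  expect_true(all(ds0$tumor_events == 0) && all(ds0$normal_events == 0))

  # null moments: group means within 3 sqrt(lambda/n) of lambda
  cfg <- sim_config(n_tumor = 2000, n_normal = 2000, n_genes = 1,
                    null_intensity = 0.05, seed = 11)
  ds <- simulate_rare_variants(cfg)
  tol <- 3 * sqrt(0.05 / 2000)
  expect_lt(abs(mean(ds$tumor_events) - 0.05), tol)
  expect_lt(abs(mean(ds$normal_events) - 0.05), tol)

  # planted excess appears only in the tumor group
  cfg_e <- sim_config(n_tumor = 4000, n_normal = 4000, n_genes = 2,
                      null_intensity = 0.05,
                      effect_map = c(G0001 = 0.10), seed = 12)
  ds_e <- simulate_rare_variants(cfg_e)
  expect_lt(abs(mean(ds_e$tumor_events[, "G0001"]) - 0.15),
            4 * sqrt(0.15 / 4000))
  expect_lt(abs(mean(ds_e$normal_events[, "G0001"]) - 0.05),
            4 * sqrt(0.05 / 4000))
  expect_identical(attr(ds_e, "truth")$effect_genes, "G0001")

  # reproducibility: same config, same draw
  expect_identical(simulate_rare_variants(cfg_e)$tumor_events,
                   ds_e$tumor_events)
  # negative intensity rejected at config time
  expect_error(sim_config(null_intensity = -0.1))
})

test_that("ggm generator draws from the specified precision matrix", {
  # single planted partial correlation recovered by covariance inversion
  spec <- ggm_spec(3, data.frame(i = 1, j = 2, rho = 0.5))
  cfg <- sim_config(mrna_ggm = spec, seed = 5)
  x <- simulate_expression_ggm(cfg, 5000, "mrna")
  expect_lt(abs(empirical_partial_cor(x, 1, 2) - 0.5), 0.05)

  # chain 1-2-3: partial correlation (1,3) given 2 vanishes
  chain <- ggm_spec(3, data.frame(i = c(1, 2), j = c(2, 3),
                                  rho = c(0.5, 0.5)))
  xc <- simulate_expression_ggm(sim_config(mrna_ggm = chain, seed = 6),
                                5000, "mrna")
  expect_lt(abs(empirical_partial_cor(xc, 1, 3)), 0.05)
  # but the marginal correlation (1,3) does not vanish
  expect_gt(abs(stats::cor(xc[1, ], xc[3, ])), 0.1)

  # diagonal precision: empirical correlations shrink with n
  ind <- ggm_spec(4)
  xi <- simulate_expression_ggm(sim_config(mrna_ggm = ind, seed = 7),
                                5000, "mrna")
  cc <- stats::cor(t(xi))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.06)

  # non-positive-definite specification rejected (chain with rho 0.9 has a
  # negative eigenvalue 1 - 0.9 sqrt(2))
  expect_error(ggm_spec(3, data.frame(i = c(1, 2), j = c(2, 3),
                                      rho = c(0.9, 0.9))),
               "positive-definite")
  # truth ledger records the planted edges
  expect_identical(attr(x, "truth")$a, spec$features[1])
})

test_that("mirna regulation plants repressive effects at the stated R2", {
  spec <- ggm_spec(2, features = c("mir-A", "mir-B"))
  gspec <- ggm_spec(3, features = c("GA", "GB", "GC"))
  n <- 237
  base_cfg <- function(ts, seed = 21)
    sim_config(mrna_ggm = gspec, mirna_ggm = spec, target_spec = ts,
               seed = seed)

  # empty spec: matrix unchanged
  cfg <- base_cfg(NULL)
  mrna <- simulate_expression_ggm(cfg, n, "mrna")
  mirna <- simulate_expression_ggm(cfg, n, "mirna")
  expect_identical(simulate_mirna_regulation(cfg, mrna, mirna), mrna)

  # noiseless effect -1: exact line with slope -1, R2 = 1
  ts1 <- data.frame(mirna = "mir-A", mrna = "GA", effect = -1,
                    noise_sd = 0)
  out1 <- simulate_mirna_regulation(base_cfg(ts1), mrna, mirna)
  r1 <- regress_pair(out1["GA", ], mirna["mir-A", ])
  expect_equal(r1$coefficient, -1, tolerance = 1e-10)
  expect_equal(r1$r_squared, 1, tolerance = 1e-10)

  # effect sized for R2 = 0.33 (strongest verified pair): recovered
  eff <- effect_for_r2(0.33, var_x = stats::var(mirna["mir-A", ]),
                       noise_sd = 1)
  ts2 <- data.frame(mirna = "mir-A", mrna = "GA", effect = eff,
                    noise_sd = 1)
  out2 <- simulate_mirna_regulation(base_cfg(ts2), mrna, mirna)
  r2 <- regress_pair(out2["GA", ], mirna["mir-A", ])
  expect_lt(abs(r2$r_squared - 0.33), 0.05)
  expect_lt(r2$coefficient, 0)
  expect_equal(attr(out2, "truth")$realized_r2, r2$r_squared,
               tolerance = 1e-10)

  # positive effects are rejected: targets are repressive by construction
  expect_error(base_cfg(data.frame(mirna = "mir-A", mrna = "GA",
                                   effect = 0.5, noise_sd = 1)),
               "negative")
})

test_that("eqtl generator shifts expression additively per mutated allele", {
  cfg <- sim_config(n_tumor = 50, n_normal = 50, n_genes = 2,
                    null_intensity = 0.5,
                    mrna_ggm = ggm_spec(2, features = c("GA", "GB")),
                    eqtl_spec = data.frame(gene = "G0001", target = "GA",
                                           effect = 2),
                    seed = 31)
  muts <- simulate_rare_variants(cfg)
  # noiseless construction: start from a zero matrix
  expr <- matrix(0, 2, 50,
                 dimnames = list(c("GA", "GB"), rownames(muts$tumor_events)))
  out <- simulate_eqtl_effects(cfg, muts, expr)
  dose <- collapse_counts(muts, "T_a")$tumor[, "G0001"]
  r <- eqtl_regression(out["GA", ], dose)
  expect_equal(r$coefficient, 2, tolerance = 1e-12)
  expect_true(all(out["GB", ] == 0))
  # unknown names rejected
  bad <- cfg; bad$eqtl_spec$target <- "NOPE"
  expect_error(simulate_eqtl_effects(bad, muts, expr), "NOPE")
})

test_that("survival generator obeys the proportional-hazards model", {
  n <- 1000
  covs <- matrix(stats::rnorm(n), n, 1, dimnames = list(NULL, "mirX"))
  # null: hazard ratio near 1
  cfg0 <- sim_config(survival_spec = list(baseline_hazard = 0.1,
                                          log_hazard = c(mirX = 0),
                                          censor_rate = 0.2), seed = 41)
  s0 <- simulate_survival(cfg0, covs)
  fit0 <- cox_univariate(s0$time, s0$event, covs[, 1])
  expect_lt(abs(fit0$log_hr), 0.15)

  # hazard ratio 1.35 recovered within 15 percent
  cfg1 <- sim_config(survival_spec = list(baseline_hazard = 0.1,
                                          log_hazard = c(mirX = log(1.35)),
                                          censor_rate = 0.2), seed = 42)
  s1 <- simulate_survival(cfg1, covs)
  fit1 <- cox_univariate(s1$time, s1$event, covs[, 1])
  expect_lt(abs(fit1$hr - 1.35) / 1.35, 0.15)

  # no censoring: every event observed
  cfg2 <- sim_config(survival_spec = list(baseline_hazard = 0.1,
                                          log_hazard = c(mirX = 0),
                                          censor_rate = 0), seed = 43)
  expect_true(all(simulate_survival(cfg2, covs)$event == 1))
  # censoring rate roughly realized
  expect_lt(abs(mean(s0$event) - 0.8), 0.06)
  # invalid baseline rejected
  expect_error(sim_config(survival_spec = list(baseline_hazard = -1,
                                               log_hazard = numeric(),
                                               censor_rate = 0)))
})
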