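test_that("simulated genotypes hit their target MAFs in Hardy-Weinberg", {
  set.seed(71)
  spec <- scenario_spec("gaussian", n = 3000, l_snps = 60)
  g <- simulate_genotypes(spec)
  expect_equal(dim(g$dosages), c(3000, 60))
  # per-SNP empirical MAF close to binomial expectation around the draw
  expect_true(all(g$maf >= 0), all(g$maf <= 0.5))
  hwe_p <- vapply(seq_len(60), function(l) {
    d <- g$dosages[, l]
    hwe_test(sum(d == 2), sum(d == 1), sum(d == 0))
  }, numeric(1))
  expect_gte(mean(hwe_p > 1e-4), 0.99)
  # no LD: adjacent correlations near zero
  cc <- sapply(1:59, function(l) cor(g$dosages[, l], g$dosages[, l + 1]))
  expect_lt(max(abs(cc)), 4 / sqrt(3000))
})

test_that("autoregressive LD induces adjacent-SNP correlation, HWE margins hold", {
  set.seed(72)
  spec <- scenario_spec("gaussian", n = 4000, l_snps = 40, ld_rho = 0.8)
  g <- simulate_genotypes(spec)
  cc <- sapply(1:39, function(l) cor(g$dosages[, l], g$dosages[, l + 1]))
  expect_gt(mean(cc), 0.3)
  hwe_p <- vapply(seq_len(40), function(l) {
    d <- g$dosages[, l]
    hwe_test(sum(d == 2), sum(d == 1), sum(d == 0))
  }, numeric(1))
  expect_gte(mean(hwe_p > 1e-4), 0.95)
})

test_that("the simulated exposure is Bernoulli at the requested prevalence", {
  expect_equal(simulate_environment(50, 0), rep(0L, 50))
  set.seed(73)
  e <- simulate_environment(16555, 0.248)
  expect_lt(abs(mean(e) - 0.248), 3 * sqrt(0.248 * 0.752 / 16555))
  # independent of genotypes by construction
  g <- random_panel(2000, 5)
  e2 <- simulate_environment(2000, 0.3)
  expect_lt(max(abs(cor(g$dosages, e2))), 4 / sqrt(2000))
})

test_that("null binary traits hit the 5% prevalence from the logit intercept", {
  expect_equal(round(prevalence_intercept(0.05), 2), -2.94)
  set.seed(74)
  spec <- scenario_spec("binomial", n = 20000, l_snps = 10)
  g <- simulate_genotypes(spec)
  e <- simulate_environment(20000, 0.248)
  tr <- simulate_traits(g, e, spec)
  expect_lt(abs(mean(tr$y) - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
  expect_equal(tr$truth_idx, integer(0))
})

test_that("interaction effects honour the requested range and sign balance", {
  set.seed(75)
  spec <- scenario_spec("binomial", n = 500, l_snps = 100, d = 20)
  g <- simulate_genotypes(spec)
  e <- simulate_environment(500, 0.248)
  tr <- simulate_traits(g, e, spec)
  expect_equal(length(tr$truth_idx), 20)
  expect_true(all(abs(tr$beta_ge) >= log(1.2) & abs(tr$beta_ge) <= log(1.4)))
  expect_equal(sum(tr$beta_ge > 0), 10)

  # main-effect structure: d/2 main-only, d/2 both, d interaction-only
  spec_m <- scenario_spec("gaussian", n = 500, l_snps = 100, d = 20,
                          main_effects = TRUE)
  tr_m <- simulate_traits(g, e, spec_m)
  expect_equal(length(tr_m$beta_g), 20)    # main-only + both
  expect_equal(length(tr_m$beta_ge), 20)   # both + interaction-only
  both <- intersect(names(tr_m$beta_g), names(tr_m$beta_ge))
  expect_equal(length(both), 10)
  conc <- sign(tr_m$beta_g[both]) * sign(tr_m$beta_ge[both])
  expect_equal(sum(conc > 0), 5)           # half concordant
  expect_equal(length(tr_m$truth_idx), 20)
  expect_false(any(setdiff(names(tr_m$beta_g), both) %in%
                     as.character(tr_m$truth_idx)))
})

test_that("continuous trait variance matches the plug-in oracle", {
  set.seed(76)
  expect_warning(spec <- scenario_spec("gaussian", n = 20000, l_snps = 50,
                                       d = 20, effect_range = c(0.3, 0.5)),
                 "standard tiers")
  g <- simulate_genotypes(spec)
  e <- simulate_environment(20000, 0.248)
  tr <- simulate_traits(g, e, spec)
  ge <- g$dosages[, tr$truth_idx, drop = FALSE] * e
  b <- tr$beta_ge[order(as.integer(names(tr$beta_ge)))]
  # plug-in variance of the linear predictor (shared E couples the terms)
  expected_var <- 1 + as.numeric(t(b) %*% cov(ge) %*% b)
  expect_lt(abs(var(tr$y) / expected_var - 1), 0.05)
})

test_that("pooled sensitivity and PPV follow their definitions", {
  res <- sensitivity_ppv(true_found = c(2, 1), found = c(2, 1),
                         reps = 2, d = 3)
  expect_equal(res$sensitivity, 0.5)
  expect_equal(res$ppv, 1)
  expect_equal(res$fdp, 0)
  res0 <- sensitivity_ppv(c(0, 0), c(0, 0), 2, 3)
  expect_equal(res0$sensitivity, 0)
  expect_true(is.na(res0$ppv))
  expect_true(is.na(res0$fdp))
  res_mix <- sensitivity_ppv(c(3, 1), c(5, 3), 2, 4)
  expect_equal(res_mix$ppv, 0.5)
  expect_equal(res_mix$fdp, 0.5)
})

test_that("study harnesses are reproducible from the scenario seed", {
  spec <- scenario_spec("gaussian", n = 300, l_snps = 40, reps = 3, seed = 9)
  a <- run_type1_study(spec, methods = c("adabf", "grs_m"), b = 150)
  b <- run_type1_study(spec, methods = c("adabf", "grs_m"), b = 150)
  expect_identical(a$rates, b$rates)
  expect_identical(a$p_adabf, b$p_adabf)

  spec_p <- scenario_spec("gaussian", n = 300, l_snps = 40, d = 4,
                          effect_range = c(0.05, 0.07),
                          reps = 3, seed = 10)
  pa <- run_power_study(spec_p, methods = c("adabf", "bh"), b = 150)
  pb <- run_power_study(spec_p, methods = c("adabf", "bh"), b = 150)
  expect_identical(pa$power, pb$power)
  expect_identical(pa$log, pb$log)
})

test_that("BON never out-selects BH on the same scan", {
  set.seed(77)
  spec <- suppressWarnings(
    scenario_spec("gaussian", n = 600, l_snps = 50, d = 6,
                  effect_range = c(0.2, 0.3), reps = 4, seed = 12))
  res <- run_power_study(spec, methods = c("bon", "bh"), b = 150)
  expect_true(all(res$log$bon_found <= res$log$bh_found))
  expect_true(all(res$log$bon_true <= res$log$bh_true))
  pin <- res$pinpoint
  sens_bon <- pin$sensitivity[pin$method == "BON"]
  sens_bh <- pin$sensitivity[pin$method == "BH"]
  expect_lte(sens_bon, sens_bh)
})
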