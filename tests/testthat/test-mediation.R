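test_that("quasi-Bayesian ACME agrees with the product-of-coefficients oracle", {
  d <- mediation_data(n = 300, a = 0.5, b = 0.3, cp = 0.1, seed = 4)
  med <- fit_mediation(d, "t", "m", "y", n_sims = 5000, seed = 1)
  a_hat <- coef(lm(m ~ t, d))[["t"]]
  out_hat <- coef(lm(y ~ t + m, d))
  # MC mean of a*b vs analytic product, within 3 MC standard errors
  draws_se <- sqrt((abs(med$acme_ci[2] - med$acme_ci[1]) / 3.92)^2 / 5000)
  expect_lt(abs(med$acme - a_hat * out_hat[["m"]]), 3 * draws_se + 1e-3)
  expect_lt(abs(med$ade - out_hat[["t"]]), 0.01)
  # linear no-interaction identity: acme + ade = coefficient of t in y ~ t
  expect_equal(med$acme + med$ade, med$total)
  expect_lt(abs(med$total - med$total_model_coef), 0.01)
  expect_equal(med$prop_mediated, med$acme / med$total)
})

test_that("mediation inference is deterministic given a seed and validates inputs", {
  d <- mediation_data(n = 200, seed = 7)
  m1 <- fit_mediation(d, "t", "m", "y", n_sims = 500, seed = 3)
  m2 <- fit_mediation(d, "t", "m", "y", n_sims = 500, seed = 3)
  expect_identical(m1[c("acme", "ade", "total", "p_acme", "acme_ci")],
                   m2[c("acme", "ade", "total", "p_acme", "acme_ci")])
  expect_error(fit_mediation(d, "t", "m", "y", n_sims = 50), "n_sims")
  d$m <- 1
  expect_error(fit_mediation(d, "t", "m", "y"), "constant")
})

test_that("null mediation (b = 0) yields a near-zero ACME with covering CI", {
  d <- mediation_data(n = 500, a = 0.5, b = 0, cp = 0.3, seed = 11)
  med <- fit_mediation(d, "t", "m", "y", n_sims = 2000, seed = 2)
  expect_lt(abs(med$acme), 0.05)
  expect_true(med$acme_ci[1] <= 0 && med$acme_ci[2] >= 0)
  expect_gt(med$p_acme, 0.05)
})

test_that("ACME sign matches the sign of the coefficient product", {
  for (s in 1:5) {
    sgn <- if (s %% 2) 1 else -1
    d <- mediation_data(n = 400, a = 0.6 * sgn, b = 0.5, cp = 0, seed = 20 + s)
    med <- fit_mediation(d, "t", "m", "y", n_sims = 500, seed = s)
    expect_equal(sign(med$acme), sgn)
  }
})

test_that("chain mediation emits one result per consecutive triple", {
  st <- small_study(seed = 41, n = 250,
                    effects = effect_spec(trait_to_module = c(m1 = 0.4),
                                          module_to_tau = c(m1 = 0.4),
                                          tau_to_slope = 0.015,
                                          slope_to_ad = 1.5))
  med <- chain_mediation(st$data, c("neuroticism", "m1", "tau", "cog_slope", "ad"),
                         n_sims = 200, seed = 6)
  expect_length(med, 3)
  expect_equal(names(med),
               c("neuroticism->m1->tau", "m1->tau->cog_slope",
                 "tau->cog_slope->ad"))
  expect_equal(med[[3]]$outcome_family, "binomial")
  expect_equal(med[[1]]$outcome_family, "gaussian")
  expect_error(chain_mediation(st$data, c("neuroticism", "m1")), "3 variables")
  expect_error(chain_mediation(st$data, c("neuroticism", "m1", "ghost")),
               "ghost")
})

test_that("a zeroed middle link silences downstream mediation", {
  st <- small_study(seed = 43, n = 400,
                    effects = effect_spec(trait_to_module = c(m1 = 0.5),
                                          module_to_tau = numeric(),  # broken
                                          tau_to_slope = 0.02))
  med <- chain_mediation(st$data, c("neuroticism", "m1", "tau", "cog_slope"),
                         n_sims = 500, seed = 8)
  # m1 -> tau link absent: both triples touching it carry null ACME
  expect_gt(med[["neuroticism->m1->tau"]]$p_acme, 0.05)
  expect_true(med[["m1->tau->cog_slope"]]$acme_ci[1] <= 0 &&
                med[["m1->tau->cog_slope"]]$acme_ci[2] >= 0)
})

test_that("direction test prefers the generating orientation", {
  d <- mediation_data(n = 500, a = 0.6, b = 0.6, cp = 0, seed = 31)
  dt <- direction_test(d, "t", "m", "y", n_sims = 500, seed = 2)
  expect_equal(dt$preferred, "forward")
  expect_lt(dt$p_forward, dt$p_reverse)

  # deterministic t -> m: the reverse mediator model is degenerate and the
  # decomposition is reported as unavailable rather than crashing
  d2 <- d
  d2$m <- 2 * d2$t
  dt2 <- direction_test(d2, "t", "m", "y", n_sims = 500, seed = 2)
  expect_true(dt2$reverse_degenerate)
  expect_true(dt2$preferred %in% c("forward", "none"))
})

test_that("IV verdicts follow the pleiotropy decision rule", {
  expect_equal(iv_verdict(0.001, 0.5, 0.05), "instrument_candidate")
  expect_equal(iv_verdict(0.006, 0.037, 0.05), "pleiotropic")
  expect_equal(iv_verdict(0.3, 0.01, 0.05), "uninformative")
  expect_equal(iv_verdict(NA, 0.01, 0.05), "uninformative")
})

test_that("pleiotropy screen detects a SNP with direct effects on both traits", {
  eff <- effect_spec(snp_effects = data.frame(
    snp_id = c("snp01", "snp01"), target = c("trait", "m1"),
    effect = c(2.5, 0.4)))
  verdicts <- vapply(1:25, function(i) {
    st <- simulate_study(cohort_config(n_subjects = 400, seed = 800 + i), eff,
                         n_genes = 40, n_modules = 4, n_snps = 3)
    iv_pleiotropy_check(st$data, st$genotypes, "snp01", "neuroticism", "m1",
                        covariates = NULL)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "pleiotropic"), 0.80)
})
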