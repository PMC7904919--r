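test_that("generate_cohort honors size, demographics and score bounds", {
  cfg <- cohort_config(n_subjects = 466, female_frac = 0.62, seed = 42)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 466)
  expect_false(anyDuplicated(co$subject_id) > 0)
  # binomial draw around 289 females: allow 4 SD
  expect_lt(abs(sum(co$sex) - 466 * 0.62), 4 * sqrt(466 * 0.62 * 0.38))
  for (tr in names(cfg$trait_means)) {
    expect_true(all(co[[tr]] >= 0 & co[[tr]] <= 48))
    expect_true(all(co[[tr]] == round(co[[tr]])))
  }
  expect_true(all(co$pmi >= 0))
})

test_that("zero-variance configuration yields identical subjects at the means", {
  cfg <- cohort_config(n_subjects = 2, female_frac = 1, white_frac = 1,
                       study_frac = 0, age_sd = 0, edu_sd = 0, pmi_sd = 0,
                       rin_sd = 0,
                       trait_means = c(neuroticism = 17),
                       trait_sds = c(neuroticism = 0),
                       n_batches = 1, seed = 5)
  co <- generate_cohort(cfg)
  expect_equal(co$age_death, rep(88, 2))
  expect_equal(co$education, rep(16.7, 2))
  expect_equal(co$neuroticism, rep(17, 2))
  expect_equal(co$sex, rep(1L, 2))
  expect_true(all(unlist(co[1, -1] == co[2, -1])))
})

test_that("identical config and seed reproduce every generated table", {
  eff <- effect_spec(trait_to_module = c(m7 = 0.2),
                     module_to_tau = c(m7 = 0.3),
                     tau_to_slope = -0.01, slope_to_ad = -1,
                     snp_effects = data.frame(snp_id = "snp01",
                                              target = "trait", effect = 1.5))
  s1 <- small_study(seed = 9, effects = eff)
  s2 <- small_study(seed = 9, effects = eff)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$pathology, s2$pathology)
  expect_identical(s1$cognition, s2$cognition)
  expect_identical(s1$data, s2$data)
  s3 <- small_study(seed = 10, effects = eff)
  expect_false(identical(s1$expr, s3$expr))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(female_frac = 1.2), "female_frac")
  expect_error(cohort_config(age_sd = -1), "age_sd")
  expect_error(cohort_config(trait_sds = c(neuroticism = -2),
                             trait_means = c(neuroticism = 17)), "trait_sds")
})

test_that("expression generator builds module structure with correct sizes", {
  co <- generate_cohort(cohort_config(n_subjects = 120, seed = 2))
  expect_error(generate_expression(co, n_genes = 5, n_modules = 10),
               "n_modules")
  ex <- generate_expression(co, n_genes = 1348, n_modules = 47, seed = 7)
  sizes <- table(ex$modules$module_id)
  expect_equal(sum(sizes), 1348)
  expect_equal(length(sizes), 47)
  ex_bg <- generate_expression(co, n_genes = 1348, n_modules = 47,
                               background_frac = 0.15, seed = 7)
  expect_lte(sum(table(ex_bg$modules$module_id)), 1348)
  expect_equal(nrow(ex_bg$expr), 1348)

  # within-module gene-gene correlation exceeds between-module correlation
  m1 <- ex$modules$gene_id[ex$modules$module_id == "m1"][1:8]
  m2 <- ex$modules$gene_id[ex$modules$module_id == "m2"][1:8]
  cm <- cor(t(ex$expr[c(m1, m2), ]))
  within <- mean(cm[1:8, 1:8][upper.tri(cm[1:8, 1:8])])
  between <- mean(abs(cm[1:8, 9:16]))
  expect_gt(within, between + 0.1)
})

test_that("null effects leave module summaries uncorrelated with the trait", {
  st <- small_study(seed = 31, n = 400, effects = effect_spec())
  r <- cor(st$data$neuroticism, st$module_expr[st$data$subject_id, ])
  expect_true(all(abs(r) < 3 / sqrt(400)))
})

test_that("planted trait effect on a module is recovered within 2 SE", {
  eff <- effect_spec(trait_to_module = c(m7 = 0.3))
  # Independent oracle for the planted slope on the summary scale: the module
  # factor is 0.3 * z(trait) + e, a member gene is loading * factor + noise,
  # and the z-mean summary therefore has expected slope per raw trait unit
  #   0.3 * E[ l / sqrt(1.09 l^2 + 1) ] / sd(trait),
  # with the expectation taken over loadings l ~ U(0.4, 0.9).
  c_bar <- integrate(function(l) l / sqrt(1.09 * l^2 + 1), 0.4, 0.9)$value / 0.5
  covered <- vapply(1:200, function(i) {
    co <- generate_cohort(cohort_config(n_subjects = 500, seed = 1000 + i))
    ex <- generate_expression(co, n_genes = 80, n_modules = 8, effects = eff,
                              seed = 2000 + i)
    me <- summarize_modules(ex$expr, ex$modules)
    d <- co
    d$m7 <- me[d$subject_id, "m7"]
    fit <- fit_linear_association(d, "m7", "neuroticism")
    truth <- 0.3 * c_bar / sd(d$neuroticism)
    abs(fit$beta - truth) < 2 * fit$se
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("genotypes follow Hardy-Weinberg dosages and plant trait effects", {
  co <- generate_cohort(cohort_config(n_subjects = 398, seed = 4))
  expect_error(generate_genotypes(co, n_snps = 3, maf = 0.6), "maf")
  expect_error(generate_genotypes(co, n_snps = 3, maf = 0), "maf")
  g <- generate_genotypes(co, n_snps = 69, maf = 0.3)
  expect_equal(dim(g$dosage), c(398, 69))
  expect_true(all(g$dosage %in% 0:2))
  expect_lt(abs(mean(g$dosage) - 0.6), 0.05)

  eff <- effect_spec(snp_effects = data.frame(snp_id = "snp01",
                                              target = "trait", effect = 2))
  g2 <- generate_genotypes(co, n_snps = 5, maf = 0.3, effects = eff)
  d <- g2$dosage[, "snp01"]
  fit <- lm(g2$cohort$neuroticism ~ d)
  expect_lt(abs(coef(fit)[2] - 2), 3 * summary(fit)$coefficients[2, 2])
})

test_that("planted SNP-module effect sign is recovered in nearly all replicates", {
  eff <- effect_spec(snp_effects = data.frame(snp_id = "snp01", target = "m1",
                                              effect = 0.25))
  hits <- vapply(1:200, function(i) {
    co <- generate_cohort(cohort_config(n_subjects = 400, seed = 5000 + i))
    g <- generate_genotypes(co, n_snps = 2, maf = 0.3, effects = eff,
                            seed = 6000 + i)
    ex <- generate_expression(co, n_genes = 20, n_modules = 2, effects = eff,
                              genotypes = g, seed = 7000 + i)
    me <- summarize_modules(ex$expr, ex$modules)
    d <- co
    d$m1 <- me[d$subject_id, "m1"]
    res <- snp_scan(g, d, outcome = "m1", covariates = NULL)
    res$beta[res$predictor == "snp01"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("downstream generator validates alignment and is exact when noiseless", {
  st <- small_study(seed = 3)
  bad <- st$module_expr
  rownames(bad)[1] <- "SXXXX"
  expect_error(generate_downstream(st$cohort, bad), "SXXXX")

  eff <- effect_spec(module_to_tau = c(m1 = 0.4), tau_to_slope = -0.02,
                     noise_sds = c(expression = 1, tau = 1e-9, abeta = 1e-9,
                                   slope = 1e-9))
  down <- generate_downstream(st$cohort, st$module_expr, eff,
                              region_noise_sd = 0, slope_sd = 1, obs_sd = 0)
  panel <- transform_pathology(down$pathology)
  tau <- panel$global$value[panel$global$mark == "TAU"]
  sl <- estimate_slopes(down$cognition)
  fit <- lm(sl$slope ~ tau)
  expect_equal(unname(coef(fit)[2]), -0.02, tolerance = 1e-6)

  # null chain: TAU independent of module summary
  down0 <- generate_downstream(st$cohort, st$module_expr, effect_spec())
  panel0 <- transform_pathology(down0$pathology)
  tau0 <- panel0$global$value[panel0$global$mark == "TAU"]
  r <- abs(cor(tau0, st$module_expr[st$cohort$subject_id, "m1"]))
  expect_lt(r, 3 / sqrt(nrow(st$cohort)))
})
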