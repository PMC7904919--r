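test_that("low-count filter applies the prevalence rule at its boundaries", {
  m <- rbind(a = c(5, 5, 5, 0, 0),
             b = c(3, 3, 3, 3, 3),
             c = c(0, 1, 0, 2, 2),
             d = c(4, 4, 4, 4, 0),
             e = c(9, 0, 0, 0, 0))
  expect_equal(filter_low_expression(m, min_reads = 4, min_subjects = 3), c("a", "d"))
  expect_equal(filter_low_expression(m["b", , drop = FALSE],
                                     min_reads = 4, min_subjects = 1),
               character(0))
  expect_equal(filter_low_expression(m[c("c", "d", "e"), ],
                                     min_reads = 4, min_subjects = 2), "d")
  expect_error(filter_low_expression(matrix(numeric(0), 0, 0)), "empty")
  expect_error(filter_low_expression(m, min_subjects = 99), "min_subjects")
})

test_that("low-count filter matches a double-loop oracle on random matrices", {
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(rnbinom(50 * 50, mu = 3, size = 1), 50, 50,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    mr <- sample(0:6, 1)
    ms <- sample(1:50, 1)
    keep <- character(0)
    for (i in 1:50) {
      cnt <- 0L
      for (j in 1:50) if (m[i, j] >= mr) cnt <- cnt + 1L
      if (cnt >= ms) keep <- c(keep, rownames(m)[i])
    }
    expect_equal(filter_low_expression(m, mr, ms), keep)
  }
})

test_that("module summaries behave as z-score means", {
  set.seed(3)
  expr <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(paste0("g", 1:5), paste0("S", 1:20)))
  asg <- data.frame(gene_id = paste0("g", 1:5),
                    module_id = c("m1", "m2", "m2", "m3", "m3"))
  me <- summarize_modules(expr, asg)
  # single-gene module equals that gene's z-score
  expect_equal(me[, "m1"], setNames(as.numeric(scale(expr["g1", ])),
                                    colnames(expr)))
  # per-column mean is ~0 for standardized genes
  expect_true(all(abs(colMeans(me)) < 1e-12))
  # permutation of gene order within modules is irrelevant
  me2 <- summarize_modules(expr, asg[c(5, 3, 1, 2, 4), ])
  expect_equal(me, me2)
  # two genes with opposite z-scores cancel
  expr2 <- rbind(g1 = 1:10, g2 = 10:1)
  me3 <- summarize_modules(expr2, data.frame(gene_id = c("g1", "g2"),
                                             module_id = "m1"))
  expect_equal(unname(me3[, "m1"]), rep(0, 10))
  # modules with no retained genes are dropped with a warning
  expect_warning(
    me4 <- summarize_modules(expr, rbind(asg, data.frame(gene_id = "gX",
                                                         module_id = "m9"))),
    "m9")
  expect_equal(colnames(me4), c("m1", "m2", "m3"))
  expect_error(summarize_modules(expr, data.frame(gene_id = "zz",
                                                  module_id = "m1")),
               "no gene")
})

test_that("eigengene summary tracks the z-mean summary up to sign", {
  st <- small_study(seed = 8, effects = effect_spec(trait_to_module = c(m1 = 0.3)))
  em <- summarize_modules(st$expr, st$modules, method = "eigengene")
  zm <- summarize_modules(st$expr, st$modules)
  expect_identical(attr(em, "method"), "eigengene")
  expect_true(all(diag(cor(em, zm)) > 0.95))
})

test_that("pathology transform applies sqrt per region and to the global mean", {
  regions <- c("MF", "EC", "SF", "CG", "CALC", "HIP", "IT", "AG")
  raw <- data.frame(subject_id = "S1", mark = "TAU", region = regions,
                    value = 1:8)
  p <- transform_pathology(raw)
  expect_equal(p$global$value, sqrt(4.5))
  expect_equal(p$global$value, 2.1213, tolerance = 1e-4)
  expect_equal(p$regional$sqrt_value, sqrt(1:8))

  raw$value <- rep(9, 8)
  expect_equal(transform_pathology(raw)$global$value, 3)
  raw$value <- rep(0, 8)
  p0 <- transform_pathology(raw)
  expect_true(all(p0$regional$sqrt_value == 0) && all(p0$global$value == 0))
  raw$value[1] <- -1
  expect_error(transform_pathology(raw), "negative")

  raw$value <- 1:8
  alt <- transform_pathology(raw, global_method = "mean_of_sqrt")
  expect_equal(alt$global$value, mean(sqrt(1:8)))
})

test_that("raising any regional burden never lowers the global transformed value", {
  regions <- c("MF", "EC", "SF", "CG", "CALC", "HIP", "IT", "AG")
  set.seed(4)
  for (i in 1:20) {
    v <- runif(8, 0, 10)
    raw <- data.frame(subject_id = "S1", mark = "TAU", region = regions,
                      value = v)
    g1 <- transform_pathology(raw)$global$value
    j <- sample(8, 1)
    raw$value[j] <- raw$value[j] + runif(1, 0, 5)
    g2 <- transform_pathology(raw)$global$value
    expect_gte(g2, g1)
  }
})

test_that("per-subject OLS slopes match lines exactly and shift-invariantly", {
  traj <- data.frame(subject_id = c("A", "A", "B", "B", "B", "C"),
                     visit_year = c(0, 1, 0, 1, 2, 0),
                     score = c(1, 0.5, 1, 2, 3, 5))
  sl <- estimate_slopes(traj)
  expect_equal(sl$slope[sl$subject_id == "A"], -0.5)
  expect_equal(sl$slope[sl$subject_id == "B"], 1.0)
  expect_true(is.na(sl$slope[sl$subject_id == "C"]))
  expect_equal(sl$n_visits, c(2L, 3L, 1L))

  shifted <- traj
  shifted$visit_year <- shifted$visit_year + 17.3
  expect_equal(estimate_slopes(shifted)$slope, sl$slope)

  dup <- rbind(traj, data.frame(subject_id = "A", visit_year = 1, score = 2))
  expect_error(estimate_slopes(dup), "duplicate")
})

test_that("noiseless planted slopes are recovered to machine precision", {
  set.seed(6)
  n <- 100
  slopes <- rnorm(n, -0.05, 0.03)
  base <- rnorm(n)
  traj <- do.call(rbind, lapply(seq_len(n), function(i) {
    yrs <- 0:(1 + (i %% 5))
    data.frame(subject_id = sprintf("S%03d", i), visit_year = yrs,
               score = base[i] + slopes[i] * yrs)
  }))
  est <- estimate_slopes(traj)
  est <- est[match(sprintf("S%03d", seq_len(n)), est$subject_id), ]
  expect_equal(est$slope, slopes, tolerance = 1e-12)
})
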