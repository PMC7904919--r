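# Shared fixture builders: everything is generated in code at test time.

# A small but fully structured synthetic study.
small_study <- function(seed = 11, n = 200, effects = effect_spec(),
                        n_genes = 80, n_modules = 8, n_snps = 5) {
  simulate_study(cohort_config(n_subjects = n, seed = seed), effects,
                 n_genes = n_genes, n_modules = n_modules, n_snps = n_snps)
}

# Direct three-variable mediation data: m = a*t + e1, y = cp*t + b*m + e2.
mediation_data <- function(n = 500, a = 0.5, b = 0.3, cp = 0.1, sd = 1,
                           seed = 1) {
  set.seed(seed)
  t <- rnorm(n)
  m <- a * t + rnorm(n, 0, sd)
  y <- cp * t + b * m + rnorm(n, 0, sd)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), t = t, m = m, y = y)
}

# Brute-force Benjamini-Hochberg: q_i = min over j with p_(j) >= p_(i) ... the
# step-up definition min_{j >= i} p_(j) * m / j, computed literally.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}
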