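# Synthetic cohort generator: a community-based aging-study lookalike
# (two joint cohorts, NEO five-factor traits, postmortem pathology in 8
# brain regions, longitudinal cognition, dosage genotypes) with planted
# effects so every downstream stage can be tested without restricted data.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the demographic structure of the autopsy cohort the
#' package emulates: 466 subjects, 62% female, mean age at death 88 (SD 6.8)
#' years, 16.7 (3.5) years of education, 99% white, two joint parent studies,
#' and five NEO-FFI personality scores on a 0--48 scale with the published
#' means/SDs (neuroticism 17 (6.5), conscientiousness 34 (5.0), extraversion
#' 30 (6.0), openness 25 (5.3), agreeableness 34 (3.9)).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param female_frac Proportion female in `[0, 1]`.
#' @param age_mean,age_sd Age at death, years.
#' @param edu_mean,edu_sd Education, years.
#' @param white_frac Proportion with `race_white = 1`.
#' @param study_frac Proportion assigned to the first parent study
#'   (`study = 1`).
#' @param trait_means,trait_sds Named numeric vectors (same names) giving the
#'   score-scale mean and SD of each personality trait.
#' @param trait_max Maximum composite trait score; scores are rounded and
#'   clipped to `[0, trait_max]`. 48 for the standard 12-item 0--4 scoring;
#'   set 36 for the alternative 0--36 presentation.
#' @param pmi_mean,pmi_sd Postmortem interval, hours (truncated at 0).
#' @param n_batches Number of RNA-seq batches (uniformly assigned).
#' @param rin_mean,rin_sd RNA integrity number.
#' @param seed Integer RNG seed for the whole simulation run; per-stage
#'   substreams are derived from it deterministically.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 466L,
                          female_frac = 0.616,
                          age_mean = 88, age_sd = 6.8,
                          edu_mean = 16.7, edu_sd = 3.5,
                          white_frac = 0.99,
                          study_frac = 0.5,
                          trait_means = c(neuroticism = 17, conscientiousness = 34,
                                          extraversion = 30, openness = 25,
                                          agreeableness = 34),
                          trait_sds = c(neuroticism = 6.5, conscientiousness = 5,
                                        extraversion = 6, openness = 5.3,
                                        agreeableness = 3.9),
                          trait_max = 48L,
                          pmi_mean = 7, pmi_sd = 4,
                          n_batches = 8L,
                          rin_mean = 7, rin_sd = 1,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), female_frac = female_frac,
              age_mean = age_mean, age_sd = age_sd,
              edu_mean = edu_mean, edu_sd = edu_sd,
              white_frac = white_frac, study_frac = study_frac,
              trait_means = trait_means, trait_sds = trait_sds,
              trait_max = trait_max,
              pmi_mean = pmi_mean, pmi_sd = pmi_sd,
              n_batches = as.integer(n_batches),
              rin_mean = rin_mean, rin_sd = rin_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("invalid cohort_config field '", nm, "': must be a proportion in [0, 1]",
           call. = FALSE)
  }
  chk_sd <- function(x, nm) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
      stop("invalid cohort_config field '", nm, "': SDs must be >= 0", call. = FALSE)
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 2L)
    stop("invalid cohort_config field 'n_subjects': need at least 2 subjects",
         call. = FALSE)
  chk_frac(cfg$female_frac, "female_frac")
  chk_frac(cfg$white_frac, "white_frac")
  chk_frac(cfg$study_frac, "study_frac")
  for (nm in c("age_sd", "edu_sd", "pmi_sd", "rin_sd")) chk_sd(cfg[[nm]], nm)
  chk_sd(cfg$trait_sds, "trait_sds")
  if (!identical(names(cfg$trait_means), names(cfg$trait_sds)))
    stop("invalid cohort_config field 'trait_sds': names must match trait_means",
         call. = FALSE)
  if (cfg$trait_max <= 0)
    stop("invalid cohort_config field 'trait_max': must be positive", call. = FALSE)
  if (cfg$n_batches < 1L)
    stop("invalid cohort_config field 'n_batches': need at least 1 batch",
         call. = FALSE)
  invisible(cfg)
}

# Deterministic per-stage substream: one master seed per run, a fixed
# offset per stage, kept under 2^31.
substream <- function(seed, stage) {
  offsets <- c(cohort = 101L, expression = 211L, genotypes = 307L,
               downstream = 401L, pipeline = 503L)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject: sex (female = 1), age at death, education,
#' race, parent study, postmortem interval, RNA-seq batch, RIN, and the five
#' personality scores. Trait scores are rounded, clipped Gaussians on the
#' configured scale; the unclipped latent draws are kept as an attribute so
#' genotype effects can be added on the latent scale before clipping.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with `n_subjects` rows; attributes `trait_latent`
#'   (matrix of unclipped latent trait draws), `trait_max` and `seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(substream(config$seed, "cohort"))
  n <- config$n_subjects
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex        = rbinom(n, 1L, config$female_frac),
    age_death  = rnorm(n, config$age_mean, config$age_sd),
    education  = rnorm(n, config$edu_mean, config$edu_sd),
    race_white = rbinom(n, 1L, config$white_frac),
    study      = rbinom(n, 1L, config$study_frac),
    pmi        = pmax(rnorm(n, config$pmi_mean, config$pmi_sd), 0),
    batch      = factor(sprintf("b%d", sample.int(config$n_batches, n, replace = TRUE)),
                        levels = sprintf("b%d", seq_len(config$n_batches))),
    rin        = rnorm(n, config$rin_mean, config$rin_sd),
    stringsAsFactors = FALSE
  )
  traits <- names(config$trait_means)
  latent <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
  for (tr in traits) {
    latent[, tr] <- rnorm(n, config$trait_means[[tr]], config$trait_sds[[tr]])
    cohort[[tr]] <- clip_score(latent[, tr], config$trait_max)
  }
  attr(cohort, "trait_latent") <- latent
  attr(cohort, "trait_max") <- config$trait_max
  attr(cohort, "seed") <- config$seed
  cohort
}

clip_score <- function(x, max_score) pmin(pmax(round(x), 0), max_score)

#' Planted-effect specification for the synthetic causal chain
#'
#' Encodes the causal chain trait -> co-expression module -> tangle (TAU)
#' pathology -> cognitive-decline slope -> AD dementia, plus per-SNP additive
#' effects. All effects default to zero (a null cohort).
#'
#' @param trait Name of the trait driving the chain.
#' @param trait_to_module Named numeric: standardized effect of the trait
#'   (per SD of trait score) on each named module's latent factor.
#' @param module_to_tau,module_to_abeta Named numeric: standardized effect of
#'   a module summary on the square-root-scale global pathology burden.
#' @param tau_to_slope Effect of the transformed global TAU burden on the
#'   cognitive slope, in slope units (score/year) per sqrt-pathology unit.
#' @param slope_to_ad Logistic coefficient of the standardized cognitive
#'   slope on the log-odds of an AD diagnosis (negative: steeper decline,
#'   higher odds).
#' @param snp_effects `data.frame` with columns `snp_id`, `target`, `effect`:
#'   `target` is `"trait"` (per-allele effect on the trait score, latent
#'   scale), a module id (per-allele effect on that module's factor), or
#'   `"TAU"`/`"ABETA"` (per-allele effect on the sqrt-scale global burden).
#' @param noise_sds Named numeric residual scales (`expression`, `tau`,
#'   `abeta`, `slope`); all must be > 0.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(trait = "neuroticism",
                        trait_to_module = numeric(),
                        module_to_tau = numeric(),
                        module_to_abeta = numeric(),
                        tau_to_slope = 0,
                        slope_to_ad = 0,
                        snp_effects = data.frame(snp_id = character(),
                                                 target = character(),
                                                 effect = numeric()),
                        noise_sds = c(expression = 1, tau = 1, abeta = 1,
                                      slope = 1)) {
  need <- c("expression", "tau", "abeta", "slope")
  miss <- setdiff(need, names(noise_sds))
  if (length(miss)) noise_sds[miss] <- 1
  if (any(noise_sds <= 0)) stop("noise_sds must all be > 0", call. = FALSE)
  if (!all(c("snp_id", "target", "effect") %in% names(snp_effects)))
    stop("snp_effects needs columns snp_id, target, effect", call. = FALSE)
  structure(list(trait = trait,
                 trait_to_module = trait_to_module,
                 module_to_tau = module_to_tau,
                 module_to_abeta = module_to_abeta,
                 tau_to_slope = tau_to_slope,
                 slope_to_ad = slope_to_ad,
                 snp_effects = snp_effects,
                 noise_sds = noise_sds[need]),
            class = "effect_spec")
}

#' Demonstration effect specification with a realistic planted chain
#'
#' A realistic configuration of the causal chain: a broad field of weak
#' trait effects across a dozen modules (the trait's diffuse transcriptomic
#' footprint), stronger effects on two neuronal modules (and negative
#' effects on two others), the
#' first module driving TAU burden, TAU steepening the decline slope, and a
#' steeper slope raising the odds of AD. Module ids refer to the sequential
#' namespace produced by [generate_expression()] with >= 13 modules.
#'
#' @param trait Trait driving the chain.
#' @return An [effect_spec()].
#' @export
rosmap_like_effects <- function(trait = "neuroticism") {
  broad <- setNames(rep(c(0.09, -0.09), 6), sprintf("m%d", 20:31))
  effect_spec(
    trait = trait,
    trait_to_module = c(c(m7 = 0.15, m6 = 0.15, m12 = -0.12, m13 = -0.12),
                        broad),
    module_to_tau = c(m7 = 0.4),
    tau_to_slope = -0.03,
    slope_to_ad = -1.2,
    snp_effects = data.frame(
      snp_id = c("snp01", "snp01"),
      target = c("trait", "m7"),
      effect = c(1.5, 0.25)
    )
  )
}

#' Generate module-structured gene expression
#'
#' Latent-factor construction: each module has a per-subject latent factor
#' (standard normal plus any planted trait/SNP effect); each member gene is
#' `loading * factor + noise` with loadings drawn uniform on `loading_range`;
#' background-pool genes are pure noise. Optionally, a negative-binomial
#' counts layer is attached through a log link on the latent level, feeding
#' the low-count QC filter; all statistics downstream consume the latent
#' (normalized-scale) matrix.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param n_genes,n_modules Gene and module counts (`n_modules <= n_genes`).
#' @param effects An [effect_spec()].
#' @param background_frac Fraction of genes left unassigned (background pool).
#' @param loading_range Range of uniform gene loadings on the module factor.
#' @param genotypes Optional dosage matrix from [generate_genotypes()], used
#'   when `effects$snp_effects` targets a module.
#' @param counts If `TRUE`, attach a negative-binomial counts matrix.
#' @param nb_size Negative-binomial size (dispersion) for the counts layer.
#' @param seed RNG seed; defaults to the cohort's expression substream.
#' @return List with `expr` (genes x subjects latent expression matrix),
#'   `modules` (`data.frame(gene_id, module_id)`, background genes omitted),
#'   and optionally `counts`.
#' @export
generate_expression <- function(cohort, n_genes = 13484L, n_modules = 47L,
                                effects = effect_spec(),
                                background_frac = 0,
                                loading_range = c(0.4, 0.9),
                                genotypes = NULL,
                                counts = FALSE, nb_size = 10,
                                seed = NULL) {
  if (n_modules > n_genes)
    stop("n_modules must not exceed n_genes", call. = FALSE)
  if (is.null(seed)) seed <- substream(attr(cohort, "seed") %||% 1L, "expression")
  set.seed(seed)
  n <- nrow(cohort)
  module_ids <- sprintf("m%d", seq_len(n_modules))

  n_bg <- round(background_frac * n_genes)
  n_assigned <- n_genes - n_bg
  assign_idx <- rep(seq_len(n_modules), length.out = n_assigned)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  module_of <- c(module_ids[assign_idx], rep(NA_character_, n_bg))

  # module latent factors with planted trait / SNP effects
  fac <- matrix(rnorm(n * n_modules), n, n_modules, dimnames = list(NULL, module_ids))
  tr <- effects$trait
  if (length(effects$trait_to_module)) {
    bad <- setdiff(names(effects$trait_to_module), module_ids)
    if (length(bad))
      stop("trait_to_module references unknown modules: ",
           paste(bad, collapse = ", "), call. = FALSE)
    z <- as.numeric(scale(cohort[[tr]]))
    for (m in names(effects$trait_to_module))
      fac[, m] <- fac[, m] + effects$trait_to_module[[m]] * z
  }
  snp_mod <- effects$snp_effects[effects$snp_effects$target %in% module_ids, ,
                                 drop = FALSE]
  if (nrow(snp_mod)) {
    if (is.null(genotypes))
      stop("snp_effects target modules but no genotypes supplied", call. = FALSE)
    dos <- genotype_dosage(genotypes)
    bad <- setdiff(snp_mod$snp_id, colnames(dos))
    if (length(bad))
      stop("snp_effects reference unknown SNPs: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (i in seq_len(nrow(snp_mod))) {
      d <- dos[, snp_mod$snp_id[i]]
      fac[, snp_mod$target[i]] <- fac[, snp_mod$target[i]] +
        snp_mod$effect[i] * (d - mean(d))
    }
  }

  loading <- runif(n_genes, loading_range[1], loading_range[2])
  expr <- matrix(rnorm(n_genes * n, 0, effects$noise_sds[["expression"]]),
                 n_genes, n, dimnames = list(gene_ids, cohort$subject_id))
  assigned <- !is.na(module_of)
  expr[assigned, ] <- expr[assigned, ] +
    loading[assigned] * t(fac)[match(module_of[assigned], module_ids), , drop = FALSE]

  out <- list(
    expr = expr,
    modules = data.frame(gene_id = gene_ids[assigned],
                         module_id = module_of[assigned],
                         stringsAsFactors = FALSE)
  )
  if (counts) {
    mu <- exp(3 + 0.4 * expr)
    out$counts <- matrix(rnbinom(length(mu), mu = mu, size = nb_size),
                         nrow(mu), ncol(mu), dimnames = dimnames(expr))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate biallelic SNP dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are Binomial(2, maf) draws per SNP. When `effects$snp_effects`
#' contains `target = "trait"` rows, the per-allele effect is added to the
#' subject's unclipped latent trait draw and the visible score re-derived
#' (rounded, clipped), so planted genetic effects act before score clipping.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param n_snps Number of SNPs.
#' @param maf Minor-allele frequency in (0, 0.5); scalar or per-SNP vector.
#' @param effects An [effect_spec()].
#' @param seed RNG seed; defaults to the cohort's genotype substream.
#' @return List of class `genotype_sim`: `dosage` (subjects x SNPs matrix,
#'   values in {0,1,2}), `maf`, and `cohort` (with trait scores updated when
#'   trait-targeted SNP effects are planted).
#' @export
generate_genotypes <- function(cohort, n_snps = 69L, maf = 0.3,
                               effects = effect_spec(), seed = NULL) {
  maf <- rep_len(maf, n_snps)
  if (any(maf <= 0 | maf >= 0.5))
    stop("maf must lie strictly in (0, 0.5)", call. = FALSE)
  if (is.null(seed)) seed <- substream(attr(cohort, "seed") %||% 1L, "genotypes")
  set.seed(seed)
  n <- nrow(cohort)
  snp_ids <- sprintf("snp%02d", seq_len(n_snps))
  dosage <- vapply(seq_len(n_snps),
                   function(j) rbinom(n, 2L, maf[j]),
                   integer(n))
  dimnames(dosage) <- list(cohort$subject_id, snp_ids)

  snp_tr <- effects$snp_effects[effects$snp_effects$target == "trait", ,
                                drop = FALSE]
  if (nrow(snp_tr)) {
    bad <- setdiff(snp_tr$snp_id, snp_ids)
    if (length(bad))
      stop("snp_effects reference unknown SNPs: ", paste(bad, collapse = ", "),
           call. = FALSE)
    latent <- attr(cohort, "trait_latent")
    tr <- effects$trait
    lat <- latent[, tr]
    for (i in seq_len(nrow(snp_tr)))
      lat <- lat + snp_tr$effect[i] * dosage[, snp_tr$snp_id[i]]
    latent[, tr] <- lat
    cohort[[tr]] <- clip_score(lat, attr(cohort, "trait_max") %||% 48L)
    attr(cohort, "trait_latent") <- latent
  }
  structure(list(dosage = dosage, maf = maf, cohort = cohort),
            class = "genotype_sim")
}

# Accept either a genotype_sim or a bare dosage matrix.
genotype_dosage <- function(g) {
  if (inherits(g, "genotype_sim")) g$dosage else as.matrix(g)
}

#' Generate pathology, longitudinal cognition and AD status
#'
#' Implements the downstream half of the planted chain. Square-root-scale
#' global pathology burdens (TAU, beta-amyloid) are driven by module
#' summaries and SNP effects; the eight regional values scatter around the
#' global burden and are squared back to the raw (non-negative) scale. Each
#' subject gets >= 2 annual cognition visits whose latent slope follows
#' `tau_to_slope * sqrt(mean raw TAU)`; AD status is a Bernoulli draw from a
#' logistic model on the (estimated, standardized) slope.
#'
#' @param cohort Cohort `data.frame` (possibly updated by
#'   [generate_genotypes()]).
#' @param module_expr Subjects x modules summary matrix, rownames = subject
#'   ids (see [summarize_modules()]).
#' @param effects An [effect_spec()].
#' @param genotypes Optional [generate_genotypes()] output for pathology-
#'   targeted SNP effects.
#' @param tau_mean,tau_sd,abeta_mean,abeta_sd Location/scale of the global
#'   sqrt-scale burdens.
#' @param region_noise_sd SD of regional scatter around the global burden,
#'   sqrt scale.
#' @param slope_mean Mean cognitive slope, score units per year.
#' @param slope_sd Residual SD of the latent slope (multiplied by
#'   `effects$noise_sds["slope"]`).
#' @param baseline_sd SD of the baseline cognition level.
#' @param obs_sd Visit-level measurement noise SD.
#' @param mean_visits Mean number of visits in excess of the guaranteed 2.
#' @param ad_prevalence Marginal AD frequency at slope = 0 effect.
#' @param seed RNG seed; defaults to the cohort's downstream substream.
#' @return List with `pathology` (long `data.frame`: subject_id, mark,
#'   region, value — raw scale), `cognition` (subject_id, visit_year, score)
#'   and `ad` (subject_id, ad).
#' @export
generate_downstream <- function(cohort, module_expr, effects = effect_spec(),
                                genotypes = NULL,
                                tau_mean = 2.0, tau_sd = 1.3,
                                abeta_mean = 1.5, abeta_sd = 1.1,
                                region_noise_sd = 0.4,
                                slope_mean = -0.05, slope_sd = 0.05,
                                baseline_sd = 0.4, obs_sd = 0.15,
                                mean_visits = 4, ad_prevalence = 0.4,
                                seed = NULL) {
  offenders <- setdiff(cohort$subject_id, rownames(module_expr))
  offenders <- c(offenders, setdiff(rownames(module_expr), cohort$subject_id))
  if (length(offenders))
    stop("module_expr subjects misaligned with cohort: ",
         paste(unique(offenders), collapse = ", "), call. = FALSE)
  module_expr <- module_expr[cohort$subject_id, , drop = FALSE]
  if (is.null(seed)) seed <- substream(attr(cohort, "seed") %||% 1L, "downstream")
  set.seed(seed)
  n <- nrow(cohort)
  regions <- c("MF", "EC", "SF", "CG", "CALC", "HIP", "IT", "AG")

  burden <- function(mod_eff, snp_target, mean, sd, noise) {
    g <- rnorm(n, 0, noise)
    if (length(mod_eff)) {
      bad <- setdiff(names(mod_eff), colnames(module_expr))
      if (length(bad))
        stop("effects reference modules absent from module_expr: ",
             paste(bad, collapse = ", "), call. = FALSE)
      for (m in names(mod_eff))
        g <- g + mod_eff[[m]] * as.numeric(scale(module_expr[, m]))
    }
    snp_p <- effects$snp_effects[effects$snp_effects$target == snp_target, ,
                                 drop = FALSE]
    if (nrow(snp_p)) {
      if (is.null(genotypes))
        stop("snp_effects target ", snp_target, " but no genotypes supplied",
             call. = FALSE)
      dos <- genotype_dosage(genotypes)
      for (i in seq_len(nrow(snp_p))) {
        d <- dos[cohort$subject_id, snp_p$snp_id[i]]
        g <- g + snp_p$effect[i] * (d - mean(d))
      }
    }
    mean + sd * g
  }

  tau_g <- burden(effects$module_to_tau, "TAU", tau_mean, tau_sd,
                  effects$noise_sds[["tau"]])
  ab_g <- burden(effects$module_to_abeta, "ABETA", abeta_mean, abeta_sd,
                 effects$noise_sds[["abeta"]])

  regional <- function(g, mark) {
    s <- pmax(rep(g, times = length(regions)) +
                rnorm(n * length(regions), 0, region_noise_sd), 0)
    data.frame(subject_id = rep(cohort$subject_id, times = length(regions)),
               mark = mark,
               region = rep(regions, each = n),
               value = s^2,
               stringsAsFactors = FALSE)
  }
  pathology <- rbind(regional(tau_g, "TAU"), regional(ab_g, "ABETA"))

  # realized transformed global TAU drives the slope (so the noiseless
  # regression of slope on transformed TAU recovers tau_to_slope exactly)
  tau_raw <- matrix(pathology$value[pathology$mark == "TAU"], n)
  tau_global_sqrt <- sqrt(rowMeans(tau_raw))
  slope <- slope_mean + effects$tau_to_slope * tau_global_sqrt +
    rnorm(n, 0, slope_sd * effects$noise_sds[["slope"]])

  n_visits <- 2L + rpois(n, mean_visits)
  baseline <- rnorm(n, 0, baseline_sd)
  cognition <- data.frame(
    subject_id = rep(cohort$subject_id, times = n_visits),
    visit_year = unlist(lapply(n_visits, function(v) seq_len(v) - 1), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  cognition$score <- rep(baseline, times = n_visits) +
    rep(slope, times = n_visits) * cognition$visit_year +
    rnorm(nrow(cognition), 0, obs_sd)

  sl <- estimate_slopes(cognition)
  slope_hat <- sl$slope[match(cohort$subject_id, sl$subject_id)]
  z <- if (sd(slope_hat) > 0) (slope_hat - mean(slope_hat)) / sd(slope_hat) else slope_hat * 0
  pr <- plogis(qlogis(ad_prevalence) + effects$slope_to_ad * z)
  ad <- data.frame(subject_id = cohort$subject_id,
                   ad = rbinom(n, 1L, pr),
                   stringsAsFactors = FALSE)
  list(pathology = pathology, cognition = cognition, ad = ad)
}

#' Simulate a complete synthetic study
#'
#' Orchestrates the full generator: cohort, genotypes (with trait effects),
#' module-structured expression, module summaries, regional pathology,
#' longitudinal cognition and AD status, all from one master seed.
#'
#' @param config A [cohort_config()].
#' @param effects An [effect_spec()].
#' @param n_genes,n_modules,n_snps,maf Sizes for the expression and genotype
#'   layers.
#' @param counts Attach the negative-binomial counts layer?
#' @param ... Passed to [generate_downstream()].
#' @return List of class `synthetic_study`: `cohort`, `genotypes`, `expr`,
#'   `modules`, `counts` (optional), `module_expr`, `pathology`, `cognition`,
#'   `ad`, plus an analysis-ready `data` frame (cohort joined with module
#'   summaries, global sqrt pathology, estimated slope and AD status).
#' @export
simulate_study <- function(config = cohort_config(), effects = effect_spec(),
                           n_genes = 2000L, n_modules = 47L,
                           n_snps = 69L, maf = 0.3, counts = FALSE, ...) {
  cohort <- generate_cohort(config)
  geno <- generate_genotypes(cohort, n_snps = n_snps, maf = maf, effects = effects)
  cohort <- geno$cohort
  ex <- generate_expression(cohort, n_genes = n_genes, n_modules = n_modules,
                            effects = effects, genotypes = geno, counts = counts)
  assignment <- ex$modules
  module_expr <- summarize_modules(ex$expr, assignment)
  down <- generate_downstream(cohort, module_expr, effects = effects,
                              genotypes = geno, ...)
  panel <- transform_pathology(down$pathology)
  slopes <- estimate_slopes(down$cognition)

  dat <- cohort
  dat <- cbind(dat, as.data.frame(module_expr)[match(dat$subject_id,
                                                     rownames(module_expr)), ,
                                               drop = FALSE])
  glob <- panel$global
  for (mk in unique(glob$mark)) {
    v <- glob$value[glob$mark == mk]
    dat[[tolower(mk)]] <- v[match(dat$subject_id, glob$subject_id[glob$mark == mk])]
  }
  dat$cog_slope <- slopes$slope[match(dat$subject_id, slopes$subject_id)]
  dat$ad <- down$ad$ad[match(dat$subject_id, down$ad$subject_id)]

  structure(list(cohort = cohort, genotypes = geno, expr = ex$expr,
                 modules = assignment, counts = ex$counts,
                 module_expr = module_expr, pathology = down$pathology,
                 pathology_panel = panel, cognition = down$cognition,
                 slopes = slopes, ad = down$ad, data = dat,
                 effects = effects, config = config),
            class = "synthetic_study")
}
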