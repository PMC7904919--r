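# Linear-structural-equation causal mediation: quasi-Bayesian ACME/ADE,
# chain mediation over the trait -> module -> TAU -> decline -> AD sequence,
# a direction (upstream/downstream) consistency check, and the
# instrumental-variable pleiotropy screen.

#' Quasi-Bayesian causal mediation for a single triple
#'
#' Fits the mediator model `M ~ T + X` (OLS) and the outcome model
#' `Y ~ T + M + X` (OLS, or logistic when the outcome is binary), draws
#' coefficient vectors from their asymptotic normal distributions, and forms
#' per draw the average causal mediation effect `ACME = a * b` (product of
#' the treatment->mediator and mediator->outcome coefficients), the average
#' direct effect `ADE = c'`, and the total effect `ACME + ADE`. Point
#' estimates are the draw means, confidence intervals the 2.5/97.5
#' percentiles, and P values two-sided Monte-Carlo tail probabilities with
#' an add-one correction. No treatment-mediator interaction is modeled. For
#' a binary outcome the effects are reported on the latent (log-odds) scale
#' of the logistic outcome model.
#'
#' @param data `data.frame` holding all variables.
#' @param treatment,mediator,outcome Column names.
#' @param covariates A [covariate_set()], character vector, or `NULL`.
#' @param n_sims Monte-Carlo draws (>= 100; default 1000).
#' @param seed RNG seed for the draws.
#' @param outcome_family `"gaussian"`, `"binomial"`, or `NULL` to detect a
#'   binary 0/1 outcome automatically.
#' @return Object of class `mediation_result`: point estimates, 95% CIs and
#'   P values for ACME, ADE and the total effect; `prop_mediated`;
#'   `total_model_coef` (coefficient of the treatment in `Y ~ T + X`,
#'   gaussian outcomes only); `n_used`, `n_sims`, `seed`.
#' @export
fit_mediation <- function(data, treatment, mediator, outcome,
                          covariates = NULL, n_sims = 1000L, seed = 1L,
                          outcome_family = NULL) {
  if (n_sims < 100L) stop("n_sims must be >= 100", call. = FALSE)
  cs <- as_covariate_set(covariates)
  for (v in c(treatment, mediator, outcome, cs$covariates))
    if (!v %in% names(data)) stop("column not found in data: ", v, call. = FALSE)
  cols <- unique(c(treatment, mediator, outcome, cs$covariates))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < length(cs$covariates) + 4L)
    stop("too few complete cases for mediation models", call. = FALSE)
  if (stats::var(d[[mediator]]) == 0)
    stop("mediator is constant", call. = FALSE)
  cs$covariates <- prune_covariates(d, cs$covariates)
  if (is.null(outcome_family)) {
    y <- d[[outcome]]
    outcome_family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }

  fm_med <- stats::reformulate(c(treatment, cs$covariates), response = mediator)
  fm_out <- stats::reformulate(c(treatment, mediator, cs$covariates),
                               response = outcome)
  med_fit <- stats::lm(fm_med, data = d)
  if (anyNA(stats::coef(med_fit)))
    stop("rank-deficient mediator model", call. = FALSE)
  out_fit <- if (outcome_family == "binomial") {
    stats::glm(fm_out, data = d, family = stats::binomial())
  } else {
    stats::lm(fm_out, data = d)
  }
  if (anyNA(stats::coef(out_fit)))
    stop("rank-deficient outcome model", call. = FALSE)

  set.seed(seed)
  a_draw <- MASS::mvrnorm(n_sims, stats::coef(med_fit),
                          stats::vcov(med_fit))[, treatment]
  out_draw <- MASS::mvrnorm(n_sims, stats::coef(out_fit), stats::vcov(out_fit))
  b_draw <- out_draw[, mediator]
  cp_draw <- out_draw[, treatment]

  acme <- a_draw * b_draw
  ade <- cp_draw
  total <- acme + ade

  total_model_coef <- NA_real_
  if (outcome_family == "gaussian") {
    tot_fit <- stats::lm(stats::reformulate(c(treatment, cs$covariates),
                                            response = outcome), data = d)
    total_model_coef <- stats::coef(tot_fit)[[treatment]]
  }

  summ <- function(x) {
    est <- mean(x)
    ci <- unname(stats::quantile(x, c(0.025, 0.975)))
    p <- min(1, 2 * (1 + min(sum(x <= 0), sum(x >= 0))) / (n_sims + 1))
    list(estimate = est, ci = ci, p = p)
  }
  s_acme <- summ(acme); s_ade <- summ(ade); s_total <- summ(total)
  structure(list(treatment = treatment, mediator = mediator, outcome = outcome,
                 covariate_set = cs$id, outcome_family = outcome_family,
                 acme = s_acme$estimate, acme_ci = s_acme$ci, p_acme = s_acme$p,
                 ade = s_ade$estimate, ade_ci = s_ade$ci, p_ade = s_ade$p,
                 total = s_total$estimate, total_ci = s_total$ci,
                 p_total = s_total$p,
                 prop_mediated = if (s_total$estimate != 0)
                   s_acme$estimate / s_total$estimate else NA_real_,
                 total_model_coef = total_model_coef,
                 n_used = n, n_sims = n_sims, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Causal mediation (", x$treatment, " -> ", x$mediator, " -> ",
      x$outcome, ", ", x$outcome_family, " outcome)\n", sep = "")
  fmtci <- function(ci) sprintf("[%.4g, %.4g]", ci[1], ci[2])
  cat(sprintf("  ACME : %.4g %s  P = %.4g\n", x$acme, fmtci(x$acme_ci), x$p_acme))
  cat(sprintf("  ADE  : %.4g %s  P = %.4g\n", x$ade, fmtci(x$ade_ci), x$p_ade))
  cat(sprintf("  Total: %.4g %s  P = %.4g\n", x$total, fmtci(x$total_ci),
              x$p_total))
  cat(sprintf("  Proportion mediated: %.3g   (n = %d, sims = %d)\n",
              x$prop_mediated, x$n_used, x$n_sims))
  invisible(x)
}

#' Chain mediation over an ordered causal sequence
#'
#' Runs one mediation fit per consecutive triple of the chain (variable i as
#' treatment, i+1 as mediator, i+2 as outcome); a 5-variable chain such as
#' trait, module, TAU, decline slope, AD yields three fits. A binary 0/1
#' terminal variable is modeled with a logistic outcome model (latent-scale
#' effects).
#'
#' @param data `data.frame` holding the chain variables.
#' @param chain Ordered character vector of >= 3 column names.
#' @param covariates A [covariate_set()] applied to every link.
#' @param n_sims,seed Passed to [fit_mediation()]; each triple gets a
#'   deterministic sub-seed.
#' @return List of [fit_mediation()] results, named
#'   `"treatment->mediator->outcome"`.
#' @export
chain_mediation <- function(data, chain, covariates = NULL, n_sims = 1000L,
                            seed = 1L) {
  if (length(chain) < 3L) stop("chain needs at least 3 variables", call. = FALSE)
  miss <- setdiff(chain, names(data))
  if (length(miss))
    stop("chain variables not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (i in seq_len(length(chain) - 2L)) {
    tr <- chain[i]; md <- chain[i + 1L]; yy <- chain[i + 2L]
    out[[paste(tr, md, yy, sep = "->")]] <-
      fit_mediation(data, tr, md, yy, covariates = covariates,
                    n_sims = n_sims, seed = seed + i)
  }
  out
}

#' Directionality consistency check for a mediation triple
#'
#' Fits the mediation in both orderings — forward (`t -> m -> y`) and
#' reverse (`m -> t -> y`) — and reports both ACME P values and which
#' ordering carries the stronger mediated signal. This is a heuristic
#' consistency check on cross-sectional data, not a proof of causal
#' direction. A reverse mediator model that is numerically deterministic
#' (zero residual variance) is flagged degenerate.
#'
#' @param data,covariates,n_sims,seed As in [fit_mediation()].
#' @param treatment,mediator,outcome Column names for the forward ordering.
#' @return List of class `direction_test`: `forward`, `reverse` (each a
#'   [fit_mediation()] result or `NULL` if degenerate), `p_forward`,
#'   `p_reverse`, `preferred` (`"forward"`, `"reverse"` or `"tie"`),
#'   `reverse_degenerate`.
#' @export
direction_test <- function(data, treatment, mediator, outcome,
                           covariates = NULL, n_sims = 1000L, seed = 1L) {
  cs <- as_covariate_set(covariates)
  cols <- unique(c(treatment, mediator, outcome, cs$covariates))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  cs$covariates <- prune_covariates(d, cs$covariates)
  rev_med <- stats::lm(stats::reformulate(c(mediator, cs$covariates),
                                          response = treatment), data = d)
  # an (almost) deterministic reverse mediator model cannot support the
  # reverse decomposition; it also signals that the outcome model will be
  # near-collinear in either ordering
  degenerate <- suppressWarnings(summary(rev_med))$r.squared > 1 - 1e-6
  fwd <- tryCatch(
    fit_mediation(data, treatment, mediator, outcome, covariates = covariates,
                  n_sims = n_sims, seed = seed),
    error = function(e) NULL)
  rev <- NULL
  if (!degenerate)
    rev <- tryCatch(
      fit_mediation(data, mediator, treatment, outcome,
                    covariates = covariates, n_sims = n_sims,
                    seed = seed + 1L),
      error = function(e) NULL)
  p_fwd <- if (is.null(fwd)) NA_real_ else fwd$p_acme
  p_rev <- if (is.null(rev)) NA_real_ else rev$p_acme
  preferred <- if (is.na(p_fwd) && is.na(p_rev)) "none"
               else if (is.na(p_rev)) "forward"
               else if (is.na(p_fwd)) "reverse"
               else if (p_fwd < p_rev) "forward"
               else if (p_fwd > p_rev) "reverse" else "tie"
  structure(list(forward = fwd, reverse = rev,
                 p_forward = p_fwd, p_reverse = p_rev,
                 preferred = preferred, reverse_degenerate = degenerate),
            class = "direction_test")
}

#' Instrumental-variable verdict from the pleiotropy decision rule
#'
#' A SNP is an `instrument_candidate` for trait -> module inference when it
#' associates with the trait but shows no trait-adjusted association with
#' the module; it is `pleiotropic` when the trait-adjusted module
#' association persists (the SNP reaches the module through a path not
#' passing through the trait, invalidating it as an instrument); otherwise
#' `uninformative`.
#'
#' @param p_snp_trait P of the SNP-trait association.
#' @param p_snp_module_adjusted P of the SNP-module association adjusted for
#'   the trait.
#' @param alpha Significance threshold.
#' @return `"instrument_candidate"`, `"pleiotropic"` or `"uninformative"`.
#' @export
iv_verdict <- function(p_snp_trait, p_snp_module_adjusted, alpha = 0.05) {
  if (is.na(p_snp_trait) || is.na(p_snp_module_adjusted)) return("uninformative")
  if (p_snp_trait < alpha && p_snp_module_adjusted >= alpha)
    "instrument_candidate"
  else if (p_snp_trait < alpha && p_snp_module_adjusted < alpha)
    "pleiotropic"
  else "uninformative"
}

#' Instrumental-variable pleiotropy screen for one SNP
#'
#' Fits three covariate-adjusted models — trait on dosage, module on dosage,
#' and module on dosage plus trait — and applies the [iv_verdict()] decision
#' rule.
#'
#' @param data Cohort `data.frame` containing trait and module columns.
#' @param genotypes [generate_genotypes()] output or dosage matrix.
#' @param snp SNP id (column of the dosage matrix).
#' @param trait,module Column names in `data`.
#' @param covariates A [covariate_set()].
#' @param alpha Significance threshold for the rule.
#' @return Object of class `iv_check`: `snp`, `p_snp_trait`,
#'   `p_snp_module_unadjusted`, `p_snp_module_adjusted`, the three fitted
#'   association rows, and `verdict`.
#' @export
iv_pleiotropy_check <- function(data, genotypes, snp, trait, module,
                                covariates = default_covariates("base"),
                                alpha = 0.05) {
  dos <- genotype_dosage(genotypes)
  if (!snp %in% colnames(dos))
    stop("SNP not found in dosage matrix: ", snp, call. = FALSE)
  if (!all(dos[, snp] %in% c(0, 1, 2)))
    stop("dosage values outside {0, 1, 2}", call. = FALSE)
  d <- data
  d[[snp]] <- dos[match(d$subject_id, rownames(dos)), snp]
  cs <- as_covariate_set(covariates)
  fit_trait <- fit_linear_association(d, outcome = trait, predictor = snp,
                                      covariates = cs)
  fit_mod <- fit_linear_association(d, outcome = module, predictor = snp,
                                    covariates = cs)
  cs_adj <- covariate_set(c(cs$covariates, trait),
                          id = paste0(cs$id, "+", trait))
  fit_mod_adj <- fit_linear_association(d, outcome = module, predictor = snp,
                                        covariates = cs_adj)
  structure(list(snp = snp,
                 p_snp_trait = fit_trait$p,
                 p_snp_module_unadjusted = fit_mod$p,
                 p_snp_module_adjusted = fit_mod_adj$p,
                 fits = rbind(fit_trait, fit_mod, fit_mod_adj),
                 alpha = alpha,
                 verdict = iv_verdict(fit_trait$p, fit_mod_adj$p, alpha)),
            class = "iv_check")
}

#' @export
print.iv_check <- function(x, ...) {
  cat("IV pleiotropy screen for", x$snp, "\n")
  cat(sprintf("  P(snp -> trait)            = %.4g\n", x$p_snp_trait))
  cat(sprintf("  P(snp -> module)           = %.4g\n", x$p_snp_module_unadjusted))
  cat(sprintf("  P(snp -> module | trait)   = %.4g\n", x$p_snp_module_adjusted))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
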