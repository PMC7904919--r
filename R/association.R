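# Covariate-adjusted linear association engine and the study-specific scans
# (trait-module, gene-level with FDR, pathology, SNP, and the trait-decline
# attenuation series).

#' Define a named covariate set
#'
#' @param covariates Character vector of covariate column names (may be
#'   empty). Factors in the data are one-hot encoded at fit time with the
#'   first level as reference.
#' @param id Short tag identifying the set (e.g. `"base"`, `"base_rna"`).
#' @return Object of class `covariate_set`.
#' @export
covariate_set <- function(covariates = character(), id = "custom") {
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates))
    stop("duplicate covariate names: ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "),
         call. = FALSE)
  structure(list(covariates = covariates, id = id), class = "covariate_set")
}

#' Standard covariate sets for the emulated study
#'
#' `"base"`: age at death, sex, education, race, study. `"base_rna"` adds the
#' RNA technical variables (postmortem interval, batch, RIN), the adjustment
#' used for all expression models. `"base_abeta"`, `"base_tau"` and
#' `"base_allpath"` extend `"base"` with global pathology burdens for the
#' attenuation analysis (the pathology columns are expected as `abeta` /
#' `tau` in the data).
#'
#' @param which One of `"base"`, `"base_rna"`, `"base_abeta"`, `"base_tau"`,
#'   `"base_allpath"`.
#' @return A [covariate_set()].
#' @export
default_covariates <- function(which = c("base", "base_rna", "base_abeta",
                                         "base_tau", "base_allpath")) {
  which <- match.arg(which)
  base <- c("age_death", "sex", "education", "race_white", "study")
  cov <- switch(which,
    base = base,
    base_rna = c(base, "pmi", "batch", "rin"),
    base_abeta = c(base, "abeta"),
    base_tau = c(base, "tau"),
    base_allpath = c(base, "abeta", "tau"))
  covariate_set(cov, id = which)
}

# Covariates with no variation on the analysis sample (e.g. race in a small,
# nearly homogeneous subsample, or a single-batch subset) carry no
# information and would make the design singular; they are dropped per model.
prune_covariates <- function(d, covs) {
  keep <- vapply(covs, function(v) {
    x <- d[[v]]
    if (is.numeric(x)) isTRUE(stats::var(x) > 0) else length(unique(x)) > 1L
  }, logical(1))
  covs[keep]
}

as_covariate_set <- function(x) {
  if (inherits(x, "covariate_set")) return(x)
  if (is.null(x)) return(covariate_set(character(), id = "none"))
  if (is.character(x)) return(covariate_set(x, id = paste(x, collapse = "+")))
  stop("cannot interpret covariates argument", call. = FALSE)
}

#' Covariate-adjusted ordinary-least-squares association
#'
#' Fits `outcome ~ predictor + covariates` with an intercept by OLS on
#' complete cases and reports the predictor's coefficient, its standard
#' error and the two-sided t-test P value. A predictor (or outcome) with no
#' variance after complete-case restriction yields a degenerate-fit flag
#' with `p = NA` rather than an error; a rank-deficient design among the
#' covariates is an error naming the collinear columns.
#'
#' @param data `data.frame` holding all columns.
#' @param outcome,predictor Column names (numeric).
#' @param covariates A [covariate_set()], character vector, or `NULL`.
#' @return One-row `data.frame` with columns `outcome`, `predictor`, `beta`,
#'   `se`, `p`, `n_used`, `covariate_set`, `degenerate`.
#' @export
fit_linear_association <- function(data, outcome, predictor, covariates = NULL) {
  cs <- as_covariate_set(covariates)
  for (v in c(outcome, predictor, cs$covariates))
    if (!v %in% names(data)) stop("column not found in data: ", v, call. = FALSE)
  cols <- unique(c(outcome, predictor, cs$covariates))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  k_min <- length(cs$covariates) + 2L
  if (n < k_min + 1L)
    stop("too few complete cases (", n, ") for ", k_min, " parameters",
         call. = FALSE)

  res <- data.frame(outcome = outcome, predictor = predictor,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n_used = n, covariate_set = cs$id, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  if (stats::var(d[[predictor]]) == 0) {
    res$degenerate <- TRUE
    return(res)
  }
  if (stats::var(d[[outcome]]) == 0) {
    res$beta <- 0
    res$degenerate <- TRUE
    return(res)
  }
  fm <- stats::reformulate(c(predictor, prune_covariates(d, cs$covariates)),
                           response = outcome)
  fit <- stats::lm(fm, data = d, singular.ok = TRUE)
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("rank-deficient design; collinear columns: ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  sfit <- suppressWarnings(summary(fit))  # degenerate fits handled below
  sm <- sfit$coefficients
  res$beta <- sm[predictor, "Estimate"]
  res$se <- sm[predictor, "Std. Error"]
  res$p <- sm[predictor, "Pr(>|t|)"]
  if (!is.finite(res$se) || res$se == 0 || !is.finite(res$p)) {
    res$degenerate <- TRUE
    res$se <- if (is.finite(res$se)) res$se else NA_real_
    # a numerically perfect fit still carries a slope: report the floor P
    # rather than NA so it is never mistaken for an untestable association
    res$p <- if (isTRUE(res$beta != 0) && sfit$sigma < 1e-12)
      .Machine$double.xmin else NA_real_
  }
  res
}

#' Trait association scan across all module summaries
#'
#' One covariate-adjusted OLS fit per module column, with the module summary
#' as outcome and the trait score as predictor; results are ordered by
#' module id.
#'
#' @param data Cohort `data.frame` containing the trait and covariates.
#' @param module_expr Subjects x modules matrix, rownames matching
#'   `data$subject_id`.
#' @param trait Trait column name.
#' @param covariates A [covariate_set()] (default `"base_rna"`).
#' @return `data.frame` of association rows, one per module.
#' @export
trait_module_scan <- function(data, module_expr, trait,
                              covariates = default_covariates("base_rna")) {
  if (!trait %in% names(data))
    stop("trait column absent from data: ", trait, call. = FALSE)
  module_expr <- as.matrix(module_expr)
  mods <- module_order(colnames(module_expr))
  d <- cbind(data,
             as.data.frame(module_expr[match(data$subject_id,
                                             rownames(module_expr)), ,
                                       drop = FALSE]))
  out <- lapply(mods, function(m)
    fit_linear_association(d, outcome = m, predictor = trait,
                           covariates = covariates))
  do.call(rbind, out)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvals Numeric vector of P values in (0, 1].
#' @return Adjusted (q) values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Gene-level trait association scan with FDR
#'
#' Per-gene covariate-adjusted association (gene expression as outcome,
#' trait as predictor) with Benjamini-Hochberg adjustment across exactly the
#' genes scanned in this call — the FDR family is the supplied gene set,
#' never the whole transcriptome implicitly.
#'
#' @param data Cohort `data.frame`.
#' @param expr Genes x subjects expression matrix.
#' @param trait Trait column name.
#' @param genes Genes to scan (default: all rows of `expr`).
#' @param covariates A [covariate_set()].
#' @return Association `data.frame` with an extra `q` column, one row per
#'   gene in `genes` order.
#' @export
gene_scan_with_fdr <- function(data, expr, trait, genes = rownames(expr),
                               covariates = default_covariates("base_rna")) {
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes))
    stop("genes absent from expression matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  em <- t(expr[genes, match(data$subject_id, colnames(expr)), drop = FALSE])
  d <- cbind(data, as.data.frame(em))
  out <- do.call(rbind, lapply(genes, function(g)
    fit_linear_association(d, outcome = g, predictor = trait,
                           covariates = covariates)))
  ok <- !out$degenerate & is.finite(out$p)
  out$q <- NA_real_
  out$q[ok] <- bh_adjust(out$p[ok])
  out
}

#' Additive-coding SNP association scan
#'
#' One covariate-adjusted OLS fit per SNP with the dosage (0/1/2) as
#' predictor. Monomorphic SNPs are flagged degenerate, never silently
#' dropped; P values from numerically perfect fits are floored at the
#' smallest positive double.
#'
#' @param genotypes [generate_genotypes()] output or a subjects x SNPs
#'   dosage matrix with subject rownames.
#' @param data Cohort `data.frame` containing `outcome` and covariates.
#' @param outcome Outcome column name.
#' @param covariates A [covariate_set()].
#' @return Association `data.frame`, one row per SNP (predictor = snp id).
#' @export
snp_scan <- function(genotypes, data, outcome,
                     covariates = default_covariates("base")) {
  dos <- genotype_dosage(genotypes)
  if (!all(dos %in% c(0, 1, 2)))
    stop("dosage values outside {0, 1, 2}", call. = FALSE)
  d <- cbind(data, as.data.frame(dos[match(data$subject_id, rownames(dos)), ,
                                     drop = FALSE]))
  out <- do.call(rbind, lapply(colnames(dos), function(s)
    fit_linear_association(d, outcome = outcome, predictor = s,
                           covariates = covariates)))
  out$p[!out$degenerate & is.finite(out$p)] <-
    pmax(out$p[!out$degenerate & is.finite(out$p)], .Machine$double.xmin)
  out
}

#' Trait-decline association under a series of covariate sets
#'
#' Refits the trait -> cognitive-slope association under each supplied
#' covariate set (typically base; base + amyloid; base + TAU; base + all
#' pathology) to expose the attenuation of the trait effect by pathology
#' adjustment.
#'
#' @param data Cohort `data.frame` containing the trait, the slope column
#'   and every covariate named by the sets.
#' @param trait Trait column name.
#' @param covariate_sets Non-empty list of [covariate_set()] objects.
#' @param outcome Slope column name (default `"cog_slope"`).
#' @return Association `data.frame`, one row per covariate set.
#' @export
trait_outcome_models <- function(data, trait, covariate_sets,
                                 outcome = "cog_slope") {
  if (!length(covariate_sets)) stop("covariate_sets must be nonempty", call. = FALSE)
  do.call(rbind, lapply(covariate_sets, function(cs)
    fit_linear_association(data, outcome = outcome, predictor = trait,
                           covariates = cs)))
}
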