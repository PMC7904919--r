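# Permutation omnibus machinery: empirical null for the full distribution of
# module P values, an omnibus P value, and empirical QQ confidence envelopes.

# Multi-response OLS of Y (n x M) on a fixed design X (n x k); returns the
# beta, se and two-sided t-test p of the column `which` of X for every
# response. One Cholesky per call — this is the hot path of the permutation
# null.
ols_scan <- function(X, Y, which = 2L) {
  n <- nrow(X); k <- ncol(X)
  R <- chol(crossprod(X))
  beta <- backsolve(R, forwardsolve(t(R), crossprod(X, Y)))
  resid <- Y - X %*% beta
  s2 <- colSums(resid^2) / (n - k)
  xii <- diag(chol2inv(R))[which]
  se <- sqrt(s2 * xii)
  tt <- beta[which, ] / se
  p <- 2 * stats::pt(-abs(tt), df = n - k)
  list(beta = beta[which, ], se = se, p = p, df = n - k)
}

# Build the (complete-case) design matrix and module response matrix for a
# trait-module scan; shared by the permutation null.
scan_design <- function(data, module_expr, trait, covariates) {
  cs <- as_covariate_set(covariates)
  module_expr <- as.matrix(module_expr)
  mods <- module_order(colnames(module_expr))
  module_expr <- module_expr[match(data$subject_id, rownames(module_expr)),
                             mods, drop = FALSE]
  cols <- unique(c(trait, cs$covariates))
  cc <- stats::complete.cases(data[cols]) & stats::complete.cases(module_expr)
  d <- data[cc, , drop = FALSE]
  fm <- stats::reformulate(c(trait, prune_covariates(d, cs$covariates)))
  X <- stats::model.matrix(fm, data = d)
  list(X = X, Y = module_expr[cc, , drop = FALSE],
       trait_col = match(trait, colnames(X)), modules = mods)
}

#' Build an empirical permutation null for a trait-module scan
#'
#' Shuffles the trait score across subjects (covariates and expression stay
#' attached to their subjects), reruns the full covariate-adjusted
#' trait-module scan, and stores all M module P values for each of the B
#' permutations. This is the empirical null underlying both the omnibus test
#' and the QQ confidence envelopes.
#'
#' @param data Cohort `data.frame`.
#' @param module_expr Subjects x modules summary matrix.
#' @param trait Trait column name (must be non-constant).
#' @param covariates A [covariate_set()].
#' @param B Number of permutations (>= 1); the study design uses 1000.
#' @param seed RNG seed for the shuffles.
#' @return Object of class `permutation_null`: list with `p` (B x M matrix
#'   of null P values), `modules`, `B`, `seed`.
#' @export
build_permutation_null <- function(data, module_expr, trait,
                                   covariates = default_covariates("base_rna"),
                                   B = 1000L, seed = 1L) {
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  des <- scan_design(data, module_expr, trait, covariates)
  if (stats::var(des$X[, des$trait_col]) == 0)
    stop("trait is constant; permutation null undefined", call. = FALSE)
  set.seed(seed)
  n <- nrow(des$X)
  P <- matrix(NA_real_, B, length(des$modules),
              dimnames = list(NULL, des$modules))
  Xp <- des$X
  for (b in seq_len(B)) {
    Xp[, des$trait_col] <- des$X[sample.int(n), des$trait_col]
    P[b, ] <- ols_scan(Xp, des$Y, which = des$trait_col)$p
  }
  structure(list(p = P, modules = des$modules, B = B, seed = seed,
                 trait = trait),
            class = "permutation_null")
}

#' Omnibus P value against the permutation null
#'
#' Summarizes the observed module P values by a single statistic and locates
#' it in the permutation distribution with the add-one estimator
#' `p = (1 + #\{b : stat_b >= stat_obs\}) / (B + 1)` (ties count as
#' exceedances; the estimator can never return 0). The default statistic is
#' the count of modules with nominal P below `alpha`; `"sumlog"`
#' (sum of -log10 P over modules) is available as a sensitivity analysis.
#'
#' @param observed Scan result `data.frame` from [trait_module_scan()], or a
#'   bare numeric vector of module P values.
#' @param null A [build_permutation_null()] result with matching M.
#' @param statistic `"count"` or `"sumlog"`.
#' @param alpha Nominal threshold used by the `"count"` statistic.
#' @return Object of class `omnibus_result`: `statistic` (observed value),
#'   `statistic_name`, `p`, `B`, `alpha`, `perm_stats`.
#' @export
omnibus_p <- function(observed, null, statistic = c("count", "sumlog"),
                      alpha = 0.05) {
  statistic <- match.arg(statistic)
  pobs <- if (is.data.frame(observed)) observed$p else as.numeric(observed)
  pobs <- pobs[!is.na(pobs)]
  if (length(pobs) != ncol(null$p))
    stop("observed scan has ", length(pobs), " P values but the null has ",
         ncol(null$p), " modules", call. = FALSE)
  stat_fun <- switch(statistic,
                     count = function(p) sum(p < alpha),
                     sumlog = function(p) sum(-log10(p)))
  stat_obs <- stat_fun(pobs)
  stat_b <- apply(null$p, 1L, stat_fun)
  p <- (1 + sum(stat_b >= stat_obs)) / (null$B + 1)
  structure(list(statistic = stat_obs, statistic_name = statistic, p = p,
                 B = null$B, alpha = alpha, perm_stats = stat_b),
            class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  cat("Permutation omnibus test (", x$statistic_name, " statistic, B = ",
      x$B, ")\n", sep = "")
  cat("  observed statistic:", format(x$statistic), "\n")
  cat("  empirical P:", format(x$p), "\n")
  invisible(x)
}

#' Empirical QQ confidence envelope from a permutation null
#'
#' For each rank r (r-th smallest P of the M modules), the envelope bounds
#' at level l are the empirical (1-l)/2 and (1+l)/2 quantiles of the r-th
#' order statistic of -log10 null P across the B permutations; the expected
#' line is -log10(r / (M + 1)). Bounds are pointwise per rank.
#'
#' @param null A [build_permutation_null()] result.
#' @param levels Envelope levels in (0, 1); default 0.90 and 0.95.
#' @return `data.frame` with columns `rank`, `expected`, `median`, and
#'   `lo`/`hi` pairs per level (e.g. `lo95`, `hi95`), all on the -log10
#'   scale.
#' @export
qq_envelope <- function(null, levels = c(0.90, 0.95)) {
  if (any(levels <= 0 | levels >= 1))
    stop("envelope levels must lie in (0, 1)", call. = FALSE)
  if (null$B < 40 && any(levels >= 0.95))
    warning("B = ", null$B, " permutations is small for a 0.95 envelope",
            call. = FALSE)
  M <- ncol(null$p)
  # order statistics per permutation: rank 1 = smallest P = largest -log10
  ord <- -log10(t(apply(null$p, 1L, sort)))
  if (null$B == 1L) ord <- matrix(ord, nrow = 1L)
  out <- data.frame(rank = seq_len(M),
                    expected = -log10(seq_len(M) / (M + 1)),
                    median = apply(ord, 2L, stats::median))
  for (l in sort(levels)) {
    qs <- apply(ord, 2L, stats::quantile,
                probs = c((1 - l) / 2, (1 + l) / 2), names = FALSE)
    tag <- formatC(round(100 * l), format = "d")
    out[[paste0("lo", tag)]] <- qs[1L, ]
    out[[paste0("hi", tag)]] <- qs[2L, ]
  }
  out
}
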