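# Deterministic data preparation: low-count gene QC, module summarization,
# pathology square-root transforms, per-subject cognitive slopes.

#' Filter genes by a prevalence-style read-count rule
#'
#' Keeps a gene if and only if at least `min_subjects` subjects have at least
#' `min_reads` reads for it. The defaults (4 reads in 100 subjects) match the
#' QC rule used to arrive at the 13,484-gene expression set this package's
#' synthetic data emulate.
#'
#' @param counts Genes x subjects non-negative integer count matrix with
#'   rownames.
#' @param min_reads Read-count threshold per subject.
#' @param min_subjects Minimum number of subjects meeting `min_reads`.
#' @return Character vector of retained gene ids, input order preserved.
#' @export
filter_low_expression <- function(counts, min_reads = 4, min_subjects = 100) {
  counts <- as.matrix(counts)
  if (!length(counts)) stop("empty count matrix", call. = FALSE)
  if (min_reads < 0) stop("min_reads must be >= 0", call. = FALSE)
  if (min_subjects > ncol(counts))
    stop("min_subjects exceeds number of subjects", call. = FALSE)
  keep <- rowSums(counts >= min_reads) >= min_subjects
  rn <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  rn[keep]
}

#' Summarize gene expression into per-module values
#'
#' Default summary is the mean over member genes of per-gene z-scores (each
#' gene standardized across subjects); `method = "eigengene"` uses the first
#' principal component of the scaled member genes instead, sign-aligned with
#' the mean z-score. Modules with no gene present in `expr` are dropped with
#' a warning.
#'
#' @param expr Genes x subjects expression matrix with gene rownames.
#' @param assignment `data.frame(gene_id, module_id)`; each gene in at most
#'   one module.
#' @param method `"zmean"` (default) or `"eigengene"`.
#' @return Subjects x modules numeric matrix (rownames = subject ids,
#'   colnames = module ids ordered by numeric suffix) with attribute
#'   `method`.
#' @export
summarize_modules <- function(expr, assignment, method = c("zmean", "eigengene")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (anyDuplicated(assignment$gene_id))
    stop("a gene maps to more than one module", call. = FALSE)
  present <- assignment$gene_id %in% rownames(expr)
  if (!any(present))
    stop("module assignment references no gene present in the expression matrix",
         call. = FALSE)
  dropped <- setdiff(unique(assignment$module_id),
                     unique(assignment$module_id[present]))
  if (length(dropped))
    warning("dropping modules with no retained genes: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  assignment <- assignment[present, , drop = FALSE]
  mods <- module_order(unique(assignment$module_id))

  z <- t(scale(t(expr[assignment$gene_id, , drop = FALSE])))
  z[is.na(z)] <- 0  # zero-variance genes contribute nothing

  out <- matrix(NA_real_, ncol(expr), length(mods),
                dimnames = list(colnames(expr), mods))
  for (m in mods) {
    zm <- z[assignment$module_id == m, , drop = FALSE]
    if (method == "zmean" || nrow(zm) == 1L) {
      out[, m] <- colMeans(zm)
    } else {
      pc <- svd(t(zm), nu = 1, nv = 0)$u[, 1]
      if (cor(pc, colMeans(zm)) < 0) pc <- -pc
      out[, m] <- pc
    }
  }
  attr(out, "method") <- method
  out
}

# order module ids m1, m2, ..., m10 by numeric suffix; non-conforming ids last
module_order <- function(ids) {
  num <- suppressWarnings(as.numeric(sub("^m", "", ids)))
  ids[order(is.na(num), num, ids)]
}

#' Square-root transform of regional pathology burdens
#'
#' Applies the field's variance-stabilizing convention: each regional value
#' is square-root transformed, and the per-subject global burden is the
#' square root of the mean of the raw regional values
#' (`global_method = "mean_of_sqrt"` switches to the mean of the transformed
#' regional values).
#'
#' @param raw Long `data.frame` with columns `subject_id`, `mark`, `region`,
#'   `value` (raw, non-negative).
#' @param global_method `"sqrt_of_mean"` (default) or `"mean_of_sqrt"`.
#' @return List of class `pathology_panel`: `regional` (input plus a
#'   transformed `sqrt_value` column) and `global`
#'   (`subject_id`, `mark`, `mean_raw`, `value` = transformed global burden).
#' @export
transform_pathology <- function(raw,
                                global_method = c("sqrt_of_mean", "mean_of_sqrt")) {
  global_method <- match.arg(global_method)
  need <- c("subject_id", "mark", "region", "value")
  if (!all(need %in% names(raw)))
    stop("raw pathology table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(raw$value < 0, na.rm = TRUE))
    stop("negative raw pathology value", call. = FALSE)
  regional <- raw
  regional$sqrt_value <- sqrt(regional$value)

  agg_raw <- aggregate(value ~ subject_id + mark, data = raw, FUN = mean)
  if (global_method == "sqrt_of_mean") {
    agg_raw$global <- sqrt(agg_raw$value)
  } else {
    agg_s <- aggregate(sqrt_value ~ subject_id + mark, data = regional, FUN = mean)
    agg_raw$global <- agg_s$sqrt_value[match(paste(agg_raw$subject_id, agg_raw$mark),
                                             paste(agg_s$subject_id, agg_s$mark))]
  }
  global <- data.frame(subject_id = agg_raw$subject_id, mark = agg_raw$mark,
                       mean_raw = agg_raw$value, value = agg_raw$global,
                       stringsAsFactors = FALSE)
  structure(list(regional = regional, global = global,
                 global_method = global_method),
            class = "pathology_panel")
}

#' Per-subject ordinary-least-squares cognitive-decline slopes
#'
#' Regresses the cognition score on visit year within each subject. Subjects
#' with fewer than two visits receive a missing slope (and are excluded from
#' downstream models by complete-case handling).
#'
#' @param traj Long `data.frame` with columns `subject_id`, `visit_year`,
#'   `score`.
#' @return `data.frame(subject_id, slope, n_visits)`, one row per subject,
#'   slope in score units per year.
#' @export
estimate_slopes <- function(traj) {
  need <- c("subject_id", "visit_year", "score")
  if (!all(need %in% names(traj)))
    stop("trajectory table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  dup <- stats::aggregate(visit_year ~ subject_id, data = traj,
                          FUN = function(y) anyDuplicated(y) > 0)
  if (any(dup$visit_year))
    stop("duplicate visit_year within subject(s): ",
         paste(dup$subject_id[dup$visit_year], collapse = ", "), call. = FALSE)
  sp <- split(traj[c("visit_year", "score")], traj$subject_id)
  slope <- vapply(sp, function(d) {
    if (nrow(d) < 2L) return(NA_real_)
    x <- d$visit_year - mean(d$visit_year)
    sum(x * d$score) / sum(x^2)
  }, numeric(1))
  data.frame(subject_id = names(sp), slope = unname(slope),
             n_visits = vapply(sp, nrow, integer(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sex-by-race demographic association test
#'
#' Builds the 2x2 sex-by-race contingency table from per-stratum counts and
#' applies a chi-square test with continuity correction, the worked
#' demographic example from the cohort this package emulates (179 males of
#' whom 176 white, 287 females of whom 285 white gives P = 0.59).
#'
#' @param demographics `data.frame` with columns `sex` (labels), `n_white`
#'   and `n_total`.
#' @return The `htest` object from [stats::chisq.test()].
#' @export
demographics_chisq <- function(demographics) {
  need <- c("sex", "n_white", "n_total")
  if (!all(need %in% names(demographics)))
    stop("demographics table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- cbind(white = demographics$n_white,
               nonwhite = demographics$n_total - demographics$n_white)
  rownames(tab) <- demographics$sex
  suppressWarnings(stats::chisq.test(tab, correct = TRUE))
}
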