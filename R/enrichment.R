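# Gene-set over-representation analysis against user-supplied collections.

#' Assemble a gene-set collection against a background universe
#'
#' Set members outside the universe are dropped with a warning; sets left
#' empty after restriction are removed (with a warning).
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Background gene id vector (typically all genes surviving
#'   the expression QC filter).
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(sets) || is.null(names(sets)))
    stop("sets must be a non-empty named list", call. = FALSE)
  restricted <- lapply(sets, function(s) intersect(unique(s), universe))
  n_drop <- sum(lengths(sets) - lengths(lapply(sets, unique))) +
    sum(lengths(lapply(sets, unique)) - lengths(restricted))
  if (sum(lengths(lapply(sets, unique)) - lengths(restricted)) > 0)
    warning("dropped gene-set members outside the universe", call. = FALSE)
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    warning("removing sets with no member in the universe: ",
            paste(names(restricted)[empty], collapse = ", "), call. = FALSE)
    restricted <- restricted[!empty]
  }
  if (!length(restricted)) stop("no usable gene sets", call. = FALSE)
  structure(list(sets = restricted, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   members).
#' @return Named list of character vectors, as required by
#'   [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' One-sided hypergeometric over-representation test
#'
#' For each set, computes the upper-tail hypergeometric (Fisher) probability
#' of observing at least the realized overlap between the query list and the
#' set, given the universe, then applies Benjamini-Hochberg adjustment
#' across all sets tested in this call. Query genes outside the universe are
#' dropped with a warning.
#'
#' @param gene_list Character vector of query gene ids.
#' @param gene_sets A [gene_set_collection()].
#' @return `data.frame` sorted by `p` with columns `set`, `hits`,
#'   `set_size`, `list_size`, `universe_size`, `p`, `q`.
#' @export
enrich <- function(gene_list, gene_sets) {
  if (!inherits(gene_sets, "gene_set_collection"))
    stop("gene_sets must be a gene_set_collection", call. = FALSE)
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, gene_sets$universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query gene(s) outside the universe",
            call. = FALSE)
    gene_list <- setdiff(gene_list, outside)
  }
  N <- length(gene_sets$universe)
  k <- length(gene_list)
  rows <- lapply(names(gene_sets$sets), function(nm) {
    s <- gene_sets$sets[[nm]]
    hits <- length(intersect(gene_list, s))
    # P(X >= hits), X ~ Hypergeometric(set, universe - set, draws = k)
    p <- stats::phyper(hits - 1L, length(s), N - length(s), k,
                       lower.tail = FALSE)
    data.frame(set = nm, hits = hits, set_size = length(s), list_size = k,
               universe_size = N, p = min(p, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}
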