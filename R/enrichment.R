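#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of a query gene list within
#' a stated universe (here typically the endogenous codeset, which is the
#' sampling frame the assay imposes). For a set with `K` universe members,
#' a query of size `n` and overlap `k` inside a universe of size `N`, the
#' raw p-value is the upper tail `P(X >= k)` of the hypergeometric
#' distribution — the observed overlap included, the standard ORA
#' convention. P-values are Benjamini-Hochberg adjusted across all tested
#' sets.
#'
#' Query genes outside the universe are dropped with a warning; sets are
#' intersected with the universe before testing and sets with no universe
#' overlap are skipped.
#'
#' @param query character vector of gene ids (e.g. a DEG list).
#' @param collection gene-set collection from [read_gmt()] (named list of
#'   character vectors).
#' @param universe character vector of all assayable gene ids.
#' @return data.frame sorted by adjusted p: `set_id`, `set_name`, `k`,
#'   `K`, `n`, `N`, `p_raw`, `p_adj`, `genes` (comma-joined overlap).
#' @export
hypergeometric_ora <- function(query, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes left inside the universe")
  }
  set_names <- attr(collection, "set_name")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id,
               set_name = if (!is.null(set_names)) unname(set_names[id]) else id,
               k = k, K = K, n = n, N = N, p_raw = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set_id = character(0), set_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p_raw)
  out <- out[order(out$p_adj, out$p_raw, out$set_id),
             c("set_id", "set_name", "k", "K", "n", "N", "p_raw", "p_adj", "genes")]
  rownames(out) <- NULL
  out
}
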