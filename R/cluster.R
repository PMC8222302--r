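#' Center and scale gene rows to unit variance
#'
#' Each gene row is centered to mean 0 and scaled to sample variance 1
#' (n - 1 denominator) across samples, so all genes contribute equally to
#' Euclidean distances. Zero-variance rows become all-zero and are
#' recorded in the `"flagged"` attribute.
#'
#' @param mat_log genes x samples numeric matrix (>= 2 samples).
#' @return scaled matrix with attribute `flagged` (character vector of
#'   constant genes).
#' @export
scale_genes <- function(mat_log) {
  if (ncol(mat_log) < 2L) stop("scaling requires >= 2 samples")
  ctr <- mat_log - rowMeans(mat_log)
  s <- sqrt(rowSums(ctr^2) / (ncol(mat_log) - 1L))
  flagged <- rownames(mat_log)[s == 0]
  s[s == 0] <- 1
  out <- ctr / s
  attr(out, "flagged") <- flagged
  out
}

# Lance-Williams update of the distance from merged cluster (i,j) to k.
lw_update <- function(linkage, dik, djk, dij, ni, nj, nk) {
  switch(linkage,
         average = (ni * dik + nj * djk) / (ni + nj),
         complete = pmax(dik, djk),
         single = pmin(dik, djk),
         ward = sqrt(((ni + nk) * dik^2 + (nj + nk) * djk^2 - nk * dij^2) /
                       (ni + nj + nk)))
}

#' Agglomerative hierarchical clustering with Euclidean distance
#'
#' Deterministic agglomeration by Lance-Williams updates: at each step the
#' pair at minimal distance is merged, ties broken by the lowest-index
#' pair, which fixes the dendrogram for any input. The result is returned
#' as a standard `hclust` object so `cutree()` and plotting work
#' unchanged.
#'
#' @param mat numeric matrix; with `axis = "samples"` (default) the
#'   columns are clustered, with `axis = "genes"` the rows.
#' @param axis which margin to cluster.
#' @param linkage `"average"` (default), `"complete"`, `"single"` or
#'   `"ward"` (Ward's method on Euclidean distances, i.e. ward.D2).
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(mat, axis = c("samples", "genes"),
                                 linkage = c("average", "complete", "single", "ward")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  m <- if (axis == "samples") t(mat) else mat
  if (any(!is.finite(m))) stop("non-finite values in clustering input")
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 items to cluster")
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  diag(d) <- Inf
  active <- seq_len(n)            # positions still live in d
  node <- -seq_len(n)             # hclust encoding of each live cluster
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    sub <- d[active, active, drop = FALSE]
    best <- min(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    # lowest-index pair first, indices in original item order
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- active[hit[1L, 1L]]; j <- active[hit[1L, 2L]]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- best
    others <- setdiff(active, c(i, j))
    d[i, others] <- d[others, i] <-
      lw_update(linkage, d[i, others], d[j, others], d[i, j],
                size[i], size[j], size[others])
    size[i] <- size[i] + size[j]
    node[i] <- step
    active <- setdiff(active, j)
  }
  order <- dendro_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = rownames(m), method = linkage,
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

# Leaf order by left-to-right traversal of the merge tree.
dendro_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) -node
    else c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' Evaluate cohort segregation of a dendrogram
#'
#' Cuts the tree into `k` clusters and cross-tabulates cluster membership
#' against cohort labels. Outliers are samples whose cluster's majority
#' label differs from their own label.
#'
#' @param hc an `hclust` object (e.g. from [hierarchical_cluster()]).
#' @param labels per-leaf labels, named by sample id or in leaf order.
#' @param k number of clusters (2 <= k <= number of leaves).
#' @return list with `assignment` (cluster per sample), `crosstab`
#'   (cluster x label table) and `outliers` (sample ids).
#' @export
evaluate_segregation <- function(hc, labels, k = 2L) {
  n_leaf <- length(hc$height) + 1L
  if (k < 2L || k > n_leaf) stop("k must lie between 2 and the leaf count")
  cl <- stats::cutree(hc, k = k)
  if (!is.null(names(labels))) labels <- labels[names(cl)]
  if (length(labels) != n_leaf || anyNA(labels))
    stop("labels must cover every leaf")
  labels <- as.character(labels)
  crosstab <- table(cluster = cl, label = labels)
  majority <- colnames(crosstab)[apply(crosstab, 1L, which.max)]
  outliers <- names(cl)[labels != majority[cl]]
  list(assignment = cl, crosstab = crosstab, outliers = outliers)
}
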