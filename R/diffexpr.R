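#' Log2 transform of nonnegative expression values
#'
#' @param x a [nanoset()] or numeric matrix with values >= 0.
#' @param offset added before the log (default 1, so zeros map to zero).
#' @return same container type, values replaced by `log2(value + offset)`.
#' @export
log_transform <- function(x, offset = 1) {
  v <- if (inherits(x, "nanoset")) ns_values(x) else x
  if (any(v < 0)) stop("log_transform requires nonnegative values")
  lv <- log2(v + offset)
  if (inherits(x, "nanoset")) ns_replace_values(x, lv) else lv
}

#' Two-group per-gene linear fit
#'
#' Per-gene difference of group means on the log2 scale with the pooled
#' residual variance — the sufficient statistics the empirical-Bayes
#' moderation step consumes.
#'
#' @param mat_log genes x samples numeric matrix of log2 expression.
#' @param labels per-sample group labels with exactly two values, each
#'   represented by at least 2 samples. The fold change is
#'   `mean(group2) - mean(group1)` with groups in factor-level order
#'   (supplied factor levels are respected; character labels sort
#'   alphabetically).
#' @return data.frame with per-gene `gene`, `log2fc`, `mean_g1`, `mean_g2`,
#'   `s2` (pooled residual variance) and `zero_variance` flag; residual df
#'   and the unscaled standard deviation `sqrt(1/n1 + 1/n2)` are attached
#'   as attributes `df_residual` and `stdev_unscaled`.
#' @export
fit_two_group <- function(mat_log, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two group labels required, got ", nlevels(labels))
  n <- table(labels)
  if (any(n < 2L)) stop("each group needs >= 2 samples (",
                        names(n)[n < 2][1L], " has ", min(n), ")")
  g1 <- mat_log[, labels == levels(labels)[1L], drop = FALSE]
  g2 <- mat_log[, labels == levels(labels)[2L], drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  rss <- rowSums((g1 - m1)^2) + rowSums((g2 - m2)^2)
  df <- sum(n) - 2L
  s2 <- rss / df
  out <- data.frame(gene = rownames(mat_log), log2fc = m2 - m1,
                    mean_g1 = m1, mean_g2 = m2, s2 = s2,
                    zero_variance = s2 == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df_residual") <- df
  attr(out, "stdev_unscaled") <- sqrt(1 / n[[1L]] + 1 / n[[2L]])
  attr(out, "groups") <- levels(labels)
  out
}

# Inverse of the trigamma function by monotone Newton iteration
# (trigamma is strictly decreasing on (0, Inf)).
trigamma_inverse <- function(y, tol = 1e-8) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < tol * x) break
    }
    x
  }, numeric(1))
}

# Method-of-moments fit of the scaled inverse chi-square prior on gene
# variances, working on z = log(s2): the prior degrees of freedom d0 solve
# a trigamma equation (inverted numerically) and the prior variance s0^2
# follows from the mean of z.
fit_variance_prior <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # variances no more dispersed than sampling noise alone: unbounded
    # prior df, scale estimated by the plain mean (unbiased under d0 = Inf)
    d0 <- Inf
    s0_sq <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderation of gene variances and moderated t
#'
#' Shrinks each gene's residual variance toward a common prior value
#' estimated from all genes (method of moments on log variances, with the
#' prior degrees of freedom obtained by inverting a trigamma equation) and
#' forms moderated t-statistics on the augmented degrees of freedom.
#'
#' Genes with zero residual variance participate with their variance
#' replaced by the smallest positive variance (and are flagged), since
#' silently dropping them would bias the prior. If all variances are
#' identical the prior degrees of freedom are unbounded, every posterior
#' variance equals the common value and a normal reference is used.
#'
#' @param s2 per-gene residual variances.
#' @param df_residual residual degrees of freedom (scalar).
#' @param log2fc per-gene effect estimates (log2 fold changes).
#' @param stdev_unscaled unscaled standard deviation of the effect
#'   (`sqrt(1/n1 + 1/n2)` for a two-group contrast).
#' @param d0 optional: force the prior degrees of freedom (0 gives the
#'   ordinary unmoderated t; `Inf` pools fully).
#' @return list with `fit` (`d0`, `s0_sq`, per-gene posterior variance
#'   `s_tilde_sq`) and `table` (per-gene `t_mod`, `df_total`, `p_raw`).
#' @export
ebayes_moderate <- function(s2, df_residual, log2fc, stdev_unscaled, d0 = NULL) {
  stopifnot(length(s2) == length(log2fc))
  if (length(s2) == 1L) {
    warning("single gene: moderation skipped, ordinary t returned")
    t_ord <- log2fc / (sqrt(s2) * stdev_unscaled)
    p <- 2 * stats::pt(-abs(t_ord), df_residual)
    return(list(fit = list(d0 = 0, s0_sq = s2, s_tilde_sq = s2),
                table = data.frame(t_mod = t_ord, df_total = df_residual, p_raw = p)))
  }
  flagged <- s2 == 0
  s2_work <- s2
  if (any(flagged)) {
    if (all(flagged)) stop("all genes have zero variance")
    s2_work[flagged] <- min(s2[!flagged])
  }
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2_work, df_residual)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else {
    s0_sq <- if (is.finite(d0) && d0 > 0)
      fit_variance_prior(s2_work, df_residual)$s0_sq else mean(s2_work)
  }
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(s2_work))
                else if (d0 == 0) s2_work
                else (d0 * s0_sq + df_residual * s2_work) / (d0 + df_residual)
  t_mod <- log2fc / (sqrt(s_tilde_sq) * stdev_unscaled)
  df_total <- df_residual + d0
  p_raw <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod))
           else 2 * stats::pt(-abs(t_mod), df_total)
  list(fit = list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde_sq,
                  zero_variance = flagged),
       table = data.frame(t_mod = t_mod, df_total = df_total, p_raw = p_raw))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the raw p-values ascending, scales the i-th by `m/i`, enforces
#' monotonicity by a cumulative minimum from the largest rank, caps at 1
#' and returns the adjusted values in the original order.
#'
#' @param p_raw numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_raw) {
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_raw)
  if (m == 0L) return(numeric(0))
  o <- order(p_raw)
  q <- p_raw[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Moderated two-group differential expression
#'
#' The full DEG chain on a normalized cohort: restrict to endogenous
#' probes, log2-transform, fit the two-group contrast, moderate the
#' variances empirically, and adjust p-values by Benjamini-Hochberg. The
#' table is sorted by adjusted p (ties by raw p, then gene id).
#'
#' @param x normalized [nanoset()] (or a plain genes x samples matrix of
#'   normalized linear-scale values).
#' @param groups per-sample labels; exactly two distinct values, in
#'   column order of `x`. The reported fold change is second level minus
#'   first level (factor-level order).
#' @param offset log2 offset (default 1).
#' @param d0 optional forced prior degrees of freedom (see
#'   [ebayes_moderate()]).
#' @return object of class `pni_de`: list with `table` (the DEG
#'   data.frame), `fit` (moderation hyperparameters), `groups`,
#'   `df_residual`.
#' @export
moderated_de <- function(x, groups, offset = 1, d0 = NULL) {
  mat <- if (inherits(x, "nanoset")) ns_values(x, "Endogenous") else x
  if (ncol(mat) != length(groups))
    stop("'groups' must have one label per sample column")
  mat_log <- log_transform(mat, offset)
  fit <- fit_two_group(mat_log, groups)
  mod <- ebayes_moderate(fit$s2, attr(fit, "df_residual"), fit$log2fc,
                         attr(fit, "stdev_unscaled"), d0 = d0)
  tab <- cbind(fit[c("gene", "log2fc", "mean_g1", "mean_g2", "s2", "zero_variance")],
               mod$table)
  tab$p_adj <- adjust_bh(tab$p_raw)
  tab <- tab[order(tab$p_adj, tab$p_raw, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fit = mod$fit, groups = attr(fit, "groups"),
                 df_residual = attr(fit, "df_residual")),
            class = "pni_de")
}

#' @export
print.pni_de <- function(x, ...) {
  cat(sprintf("<pni_de> %s vs %s: %d genes, residual df %d, prior df %.3g\n",
              x$groups[2L], x$groups[1L], nrow(x$table), x$df_residual, x$fit$d0))
  print(utils::head(x$table[, c("gene", "log2fc", "t_mod", "p_raw", "p_adj")], 6L),
        digits = 4)
  invisible(x)
}

#' @export
summary.pni_de <- function(object, fc_cut = 2, p_cut = 0.01, ...) {
  sel <- select_degs(object, fc_cut, p_cut)
  structure(list(groups = object$groups, d0 = object$fit$d0,
                 s0_sq = object$fit$s0_sq, fc_cut = fc_cut, p_cut = p_cut,
                 n_up = length(sel$up), n_down = length(sel$down),
                 n_genes = nrow(object$table)),
            class = "summary.pni_de")
}

#' @export
print.summary.pni_de <- function(x, ...) {
  cat(sprintf("Moderated DE, %s vs %s (%d genes)\n", x$groups[2L], x$groups[1L], x$n_genes))
  cat(sprintf("  prior df %.3g, prior variance %.4g\n", x$d0, x$s0_sq))
  cat(sprintf("  at |FC| > %g and adjusted p < %g: %d up, %d down\n",
              x$fc_cut, x$p_cut, x$n_up, x$n_down))
  invisible(x)
}

#' @export
coef.pni_de <- function(object, ...) {
  stats::setNames(object$table$log2fc, object$table$gene)
}

#' Volcano plot of a moderated DE fit
#' @param x a [moderated_de()] result.
#' @param fc_cut,p_cut guide lines (linear fold change and adjusted p).
#' @param ... passed to [graphics::plot()].
#' @export
plot.pni_de <- function(x, fc_cut = 2, p_cut = 0.01, ...) {
  tab <- x$table
  sig <- tab$p_adj < p_cut & abs(tab$log2fc) > log2(fc_cut)
  graphics::plot(tab$log2fc, -log10(tab$p_raw),
                 col = ifelse(sig, "firebrick", "grey50"), pch = 16, cex = 0.6,
                 xlab = "log2 fold change", ylab = "-log10 raw p", ...)
  graphics::abline(v = c(-1, 1) * log2(fc_cut), lty = 2, col = "grey40")
  invisible(x)
}

#' Select differentially expressed genes by fold change and adjusted p
#'
#' Strict thresholds on the linear fold-change scale: up-regulated genes
#' satisfy `2^log2fc > fc_cut`, down-regulated `2^log2fc < 1/fc_cut`, both
#' with `p_adj < p_cut`.
#'
#' @param de a [moderated_de()] result (or its `table`).
#' @param fc_cut linear fold-change threshold, > 1 (default 2).
#' @param p_cut adjusted-p threshold in (0, 1) (default 0.01).
#' @return list with character vectors `up` and `down`.
#' @export
select_degs <- function(de, fc_cut = 2, p_cut = 0.01) {
  tab <- if (inherits(de, "pni_de")) de$table else de
  stopifnot(fc_cut > 1, p_cut > 0, p_cut < 1)
  sig <- tab$p_adj < p_cut
  list(up = tab$gene[sig & 2^tab$log2fc > fc_cut],
       down = tab$gene[sig & 2^tab$log2fc < 1 / fc_cut])
}

#' Compare two DEG sets (Venn counts)
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list with `shared`, `unique_to_a`, `unique_to_b` and a named
#'   `counts` vector.
#' @export
compare_deg_sets <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  ua <- setdiff(set_a, set_b)
  ub <- setdiff(set_b, set_a)
  list(shared = shared, unique_to_a = ua, unique_to_b = ub,
       counts = c(shared = length(shared), unique_to_a = length(ua),
                  unique_to_b = length(ub)))
}
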