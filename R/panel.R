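#' Build the percentile-threshold gene score panel
#'
#' The panel takes the top `size` genes of a moderated DE table ranked by
#' adjusted p-value and learns, for each gene, the 95th centile (type-7
#' linear interpolation) of its normalized expression over the training
#' samples — by default the Non- and Focal-PNI cohorts, i.e. the samples
#' without extensive PNI. A sample later scores one point per panel gene
#' whose value strictly exceeds the gene's threshold.
#'
#' With `direction = "auto"`, genes that are down-regulated in the DE
#' table instead use the lower 5th centile and score when the value falls
#' strictly below it; the default `"upper"` mode scores the upper tail for
#' every gene.
#'
#' @param de a [moderated_de()] result (table sorted by adjusted p).
#' @param x normalized [nanoset()] containing the panel genes.
#' @param annotation [sample_annotation()] table for the columns of `x`;
#'   used to pick the training samples when `training` is `NULL`.
#' @param size panel size (default 10).
#' @param centile training centile level (default 0.95).
#' @param direction `"upper"` (default) or `"auto"` (tail follows the
#'   sign of the gene's fold change).
#' @param training optional explicit character vector of training sample
#'   ids, overriding the cohort-based default.
#' @return object of class `score_panel` with the ordered genes, per-gene
#'   thresholds and tail directions, centile level and training ids.
#' @export
score_panel <- function(de, x, annotation = NULL, size = 10L, centile = 0.95,
                        direction = c("upper", "auto"), training = NULL) {
  direction <- match.arg(direction)
  tab <- if (inherits(de, "pni_de")) de$table else de
  if (nrow(tab) < size) stop("DE table has fewer than ", size, " genes")
  genes <- tab$gene[seq_len(size)]
  if (is.null(training)) {
    if (is.null(annotation)) stop("either 'annotation' or 'training' must be given")
    annotation <- sample_annotation(annotation)
    training <- annotation$sample_id[annotation$cohort %in% c("NON", "FOCAL")]
  }
  training <- intersect(training, sample_ids(x))
  if (length(training) < 2L) stop("need >= 2 training samples")
  v <- ns_values(x)
  miss <- setdiff(genes, rownames(v))
  if (length(miss)) stop("panel gene missing from matrix: ", miss[1L])
  tail_dir <- rep("upper", size)
  if (direction == "auto")
    tail_dir[tab$log2fc[seq_len(size)] < 0] <- "lower"
  level <- ifelse(tail_dir == "upper", centile, 1 - centile)
  thr <- vapply(seq_len(size), function(i)
    unname(stats::quantile(v[genes[i], training], probs = level[i], type = 7)),
    numeric(1))
  structure(list(genes = genes, threshold = stats::setNames(thr, genes),
                 direction = stats::setNames(tail_dir, genes),
                 centile = centile, training = training),
            class = "score_panel")
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf("<score_panel> %d genes, centile %.2f, %d training samples\n",
              length(x$genes), x$centile, length(x$training)))
  print(data.frame(gene = x$genes, threshold = unname(x$threshold),
                   direction = unname(x$direction)), digits = 4)
  invisible(x)
}

#' Score samples against a panel
#'
#' Each sample earns one point per panel gene whose normalized value
#' strictly exceeds (upper tail) or falls strictly below (lower tail) the
#' gene's learned threshold; values exactly at the threshold score 0.
#' Training and held-out samples are scored identically.
#'
#' @param object a [score_panel()].
#' @param x normalized [nanoset()] (any samples; must contain every panel
#'   gene).
#' @param annotation optional [sample_annotation()] supplying true cohort
#'   labels for downstream evaluation.
#' @param ... unused.
#' @return object of class `score_result`: data.frame with `sample_id`,
#'   `score` (0..panel size) and `cohort` (NA when unknown); the 0/1
#'   per-gene indicator matrix is attached as attribute `indicators`.
#' @export
predict.score_panel <- function(object, x, annotation = NULL, ...) {
  v <- ns_values(x)
  miss <- setdiff(object$genes, rownames(v))
  if (length(miss)) stop("panel gene missing from matrix: ", miss[1L])
  vv <- v[object$genes, , drop = FALSE]
  up <- object$direction == "upper"
  ind <- matrix(0L, length(object$genes), ncol(vv),
                dimnames = list(object$genes, colnames(vv)))
  ind[up, ] <- (vv[up, , drop = FALSE] > object$threshold[up]) + 0L
  ind[!up, ] <- (vv[!up, , drop = FALSE] < object$threshold[!up]) + 0L
  cohort <- rep(NA_character_, ncol(vv))
  if (!is.null(annotation)) {
    annotation <- sample_annotation(annotation)
    cohort <- as.character(annotation$cohort[match(colnames(vv), annotation$sample_id)])
  }
  out <- data.frame(sample_id = colnames(vv), score = colSums(ind),
                    cohort = cohort, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "indicators") <- ind
  class(out) <- c("score_result", "data.frame")
  out
}

#' Classify scored samples at a cutoff
#'
#' A sample is called EXT-risk (positive) when its total score strictly
#' exceeds the cutoff. The default 2.5 separates integer scores <= 2 from
#' >= 3; with the alternative high-risk rule "score >= 2", use
#' `cutoff = 1.5`.
#'
#' @param result a [predict.score_panel()] result (or a data.frame with a
#'   `score` column).
#' @param cutoff classification cutoff (default 2.5).
#' @return `result` with a logical `predicted_ext` column appended.
#' @export
classify_scores <- function(result, cutoff = 2.5) {
  result$predicted_ext <- result$score > cutoff
  result
}

#' Sensitivity, specificity and predictive values
#'
#' @param predicted logical vector (positive calls).
#' @param truth true class labels; `positive` names the positive class.
#' @param positive positive-class label (default `"EXT"`).
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv` and the
#'   confusion `counts` (tp, fn, tn, fp). A metric with an empty
#'   denominator is `NA` with a warning.
#' @export
confusion_metrics <- function(predicted, truth, positive = "EXT") {
  stopifnot(length(predicted) == length(truth))
  pos <- truth == positive
  tp <- sum(predicted & pos); fn <- sum(!predicted & pos)
  tn <- sum(!predicted & !pos); fp <- sum(predicted & !pos)
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: empty denominator"); return(NA_real_) }
    num / den
  }
  list(sensitivity = safe(tp, tp + fn, "sensitivity"),
       specificity = safe(tn, tn + fp, "specificity"),
       ppv = safe(tp, tp + fp, "PPV"),
       npv = safe(tn, tn + fn, "NPV"),
       counts = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' ROC curve and AUC for a score
#'
#' Cutoffs are placed at midpoints between consecutive distinct score
#' values, plus sentinels below the minimum and above the maximum; a
#' sample is called positive when its score strictly exceeds the cutoff.
#' The AUC is the trapezoid area over (1 - specificity, sensitivity),
#' which equals the tie-corrected Mann-Whitney probability that a random
#' positive outscores a random negative (ties half-weighted).
#'
#' @param scores numeric scores.
#' @param truth class labels aligned with `scores`.
#' @param positive positive-class label (default `"EXT"`).
#' @return object of class `panel_roc`: list with `points` (data.frame of
#'   cutoff, sensitivity, specificity) and `auc`.
#' @export
roc_curve <- function(scores, truth, positive = "EXT") {
  pos <- truth == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  u <- sort(unique(scores))
  cutoffs <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
               u[length(u)] + 1)
  sens <- vapply(cutoffs, function(c) mean(scores[pos] > c), numeric(1))
  spec <- vapply(cutoffs, function(c) mean(scores[!pos] <= c), numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1L] + sens[o][-length(o)]) / 2)
  structure(list(points = data.frame(cutoff = cutoffs, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, positive = positive),
            class = "panel_roc")
}

#' @export
print.panel_roc <- function(x, ...) {
  cat(sprintf("<panel_roc> AUC = %.4f (%d cutoffs)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
plot.panel_roc <- function(x, ...) {
  graphics::plot(1 - x$points$specificity, x$points$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Null-sample calibration of a score panel
#'
#' Scores held-out null samples (drawn from the training distribution)
#' and reports the per-gene threshold exceedance rate, the score
#' distribution, and the independence binomial reference
#' `Binomial(panel size, 1 - centile)`.
#'
#' @param panel a [score_panel()].
#' @param null_x [nanoset()] of held-out null samples.
#' @return list with `exceedance` (per-gene rate), `mean_score`,
#'   `score_table` and `expected_mean` (= panel size x (1 - centile)).
#' @export
null_score_calibration <- function(panel, null_x) {
  res <- predict(panel, null_x)
  ind <- attr(res, "indicators")
  list(exceedance = rowMeans(ind),
       mean_score = mean(res$score),
       score_table = table(factor(res$score, levels = 0:length(panel$genes))),
       expected_mean = length(panel$genes) * (1 - panel$centile))
}
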