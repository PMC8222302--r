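geo_mean_cols <- function(m, pseudocount = 0) {
  if (pseudocount == 0 && any(m == 0))
    stop("zero control count encountered; geometric mean undefined ",
         "(set pseudocount = 0.5 to proceed)")
  exp(colMeans(log(m + pseudocount)))
}

#' Background correction from negative control probes
#'
#' Estimates a per-sample background level from that sample's negative
#' control probes and subtracts it from every non-control (endogenous and
#' housekeeping) probe, flooring at zero. Control rows are retained
#' unchanged for audit.
#'
#' @param x a [nanoset()] with at least one `Negative` probe.
#' @param method background statistic: `"mean"` (default, the nSolver
#'   default), `"mean_plus_2sd"`, or `"max"` of the negative controls.
#' @return list with `x` (corrected [nanoset()]) and `background`
#'   (named per-sample estimate).
#' @export
background_correct <- function(x, method = c("mean", "mean_plus_2sd", "max")) {
  method <- match.arg(method)
  neg <- ns_values(x, "Negative")
  if (nrow(neg) == 0L) stop("no Negative probes in matrix")
  bg <- switch(method,
               mean = colMeans(neg),
               mean_plus_2sd = colMeans(neg) + 2 * apply(neg, 2L, stats::sd),
               max = apply(neg, 2L, max))
  v <- ns_values(x)
  corr <- probe_class(x) %in% c("Endogenous", "Housekeeping")
  v[corr, ] <- pmax(sweep(v[corr, , drop = FALSE], 2L, bg, `-`), 0)
  list(x = ns_replace_values(x, v), background = bg)
}

normalize_by_class <- function(x, control_class, target_classes, pseudocount) {
  ctrl <- ns_values(x, control_class)
  gm <- geo_mean_cols(ctrl, pseudocount)
  factors <- mean(gm) / gm
  v <- ns_values(x)
  rows <- probe_class(x) %in% target_classes
  v[rows, ] <- sweep(v[rows, , drop = FALSE], 2L, factors, `*`)
  list(x = ns_replace_values(x, v), factors = factors)
}

#' Positive-control normalization
#'
#' Computes each sample's geometric mean of positive control probes; the
#' per-sample factor is the across-sample arithmetic mean of those
#' geometric means divided by the sample's own. All non-control probes are
#' multiplied by the factor, equalizing positive-control geometric means
#' across lanes.
#'
#' @param x a [nanoset()] with at least one `Positive` probe per sample.
#' @param pseudocount added inside the geometric mean; the default 0 is
#'   strict and errors on zero counts rather than masking a QC failure.
#' @return list with `x` (normalized [nanoset()]) and `factors`
#'   (named per-sample factor).
#' @export
positive_control_normalize <- function(x, pseudocount = 0) {
  if (nrow(ns_values(x, "Positive")) == 0L) stop("no Positive probes in matrix")
  normalize_by_class(x, "Positive", c("Endogenous", "Housekeeping"), pseudocount)
}

#' Housekeeping (CodeSet content) normalization
#'
#' Same geometric-mean factor construction as
#' [positive_control_normalize()], computed over housekeeping probes and
#' applied to endogenous probes only — the sample-specific correction
#' factor of CodeSet content normalization.
#'
#' @inheritParams positive_control_normalize
#' @return list with `x` and per-sample `factors`.
#' @export
housekeeping_normalize <- function(x, pseudocount = 0) {
  if (nrow(ns_values(x, "Housekeeping")) < 2L)
    stop("need at least 2 Housekeeping probes")
  normalize_by_class(x, "Housekeeping", "Endogenous", pseudocount)
}

#' Optional calibrator-based lot correction
#'
#' Per-probe ratio adjustment against a designated calibrator sample set:
#' each non-control probe is scaled so the calibrator samples' mean matches
#' a reference profile (by default the calibrators' own across-lot mean,
#' i.e. a no-op within a single lot). Off by default in
#' [normalize_nanostring()]; single-lot cohorts do not need it.
#'
#' @param x a [nanoset()].
#' @param calibrator_ids sample ids of the calibrator lanes.
#' @param reference named per-probe reference profile; defaults to the
#'   calibrator mean itself.
#' @return list with `x` and the per-probe `ratio` applied.
#' @export
calibrate_lot <- function(x, calibrator_ids, reference = NULL) {
  v <- ns_values(x)
  if (!all(calibrator_ids %in% colnames(v)))
    stop("unknown calibrator sample id")
  cal <- rowMeans(v[, calibrator_ids, drop = FALSE])
  if (is.null(reference)) reference <- cal
  ratio <- ifelse(cal > 0, reference[rownames(v)] / cal, 1)
  rows <- probe_class(x) %in% c("Endogenous", "Housekeeping")
  v[rows, ] <- v[rows, , drop = FALSE] * ratio[rows]
  list(x = ns_replace_values(x, v), ratio = ratio)
}

#' Full nSolver-style normalization chain
#'
#' Applies, in the documented nSolver order: background correction from
#' negative controls, positive-control normalization, then housekeeping
#' (CodeSet content) normalization. Factors outside `[0.3, 3]` are flagged
#' (QC convention) but never dropped — excluding samples is an analysis
#' decision, not a preprocessing side effect.
#'
#' @param x a raw-count [nanoset()].
#' @param background_method passed to [background_correct()].
#' @param pseudocount passed to the geometric means (default 0, strict).
#' @param calibrator_ids optional sample ids for [calibrate_lot()]
#'   (default `NULL`, off).
#' @return list with `x` (the normalized [nanoset()]) and `factors`, a
#'   per-sample data.frame of background estimates, positive and
#'   housekeeping factors and QC flags.
#' @export
normalize_nanostring <- function(x, background_method = "mean", pseudocount = 0,
                                 calibrator_ids = NULL) {
  bc <- background_correct(x, background_method)
  if (!is.null(calibrator_ids)) bc$x <- calibrate_lot(bc$x, calibrator_ids)$x
  pc <- positive_control_normalize(bc$x, pseudocount)
  hk <- housekeeping_normalize(pc$x, pseudocount)
  flag <- function(f) f < 0.3 | f > 3
  factors <- data.frame(sample_id = sample_ids(x),
                        background = unname(bc$background),
                        positive_factor = unname(pc$factors),
                        housekeeping_factor = unname(hk$factors),
                        positive_flagged = unname(flag(pc$factors)),
                        housekeeping_flagged = unname(flag(hk$factors)),
                        stringsAsFactors = FALSE)
  list(x = hk$x, factors = factors)
}
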