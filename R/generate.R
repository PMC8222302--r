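#' Configuration for the synthetic PNI cohort generator
#'
#' The generator emulates the data structure of a NanoString nCounter study
#' of head and neck cutaneous SCC stratified by perineural invasion: a
#' 740-gene endogenous codeset plus 30 housekeeping genes and spiked-in
#' positive/negative control probes, measured on 45 samples (9 Non-PNI,
#' 11 Focal-PNI, 25 Extensive-PNI). Counts are negative binomial around a
#' per-gene log-normal baseline; each sample carries a multiplicative lane
#' factor (hybridization/loading scale) and an additive Poisson background.
#' Differential expression is planted only in the EXT cohort, in two effect
#' tiers chosen so that strict fold-change filters at 2 and 3 partition the
#' planted genes into 144 and 70; Focal and Non samples are exchangeable
#' draws from the same null distribution.
#'
#' @param n_non,n_focal,n_ext cohort sizes (defaults 9, 11, 25).
#' @param n_endogenous,n_housekeeping,n_positive,n_negative codeset
#'   composition (defaults 740, 30, 6, 8).
#' @param n_de_strong number of planted genes with |log2 FC| = 2.0
#'   (default 70; these alone pass a strict fold-change-3 filter).
#' @param n_de_moderate number of planted genes with |log2 FC| = 1.3
#'   (default 74; together with the strong tier, 144 genes pass FC > 2).
#' @param frac_de_down fraction of planted genes down-regulated in EXT
#'   (default 0.06, i.e. few significant down-regulated genes).
#' @param baseline_log_mean,baseline_log_sd mean and sd of per-gene log2
#'   baseline expression for endogenous probes (defaults 7, 1.5).
#' @param hk_log_mean,hk_log_sd log2 baseline for housekeeping probes
#'   (defaults 10, 0.5): housekeeping genes are selected for high, stable
#'   expression.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2; default 0.05).
#' @param lane_factor_sd sd of per-sample log lane factor, natural-log
#'   scale (default 0.3).
#' @param background_mean mean Poisson background count added to every
#'   probe and centering the negative controls (default 10).
#' @param nerve_fraction_range range of the per-sample nerve-tissue
#'   fraction covariate, sampled independently of expression
#'   (default 0.005 to 0.80).
#' @param seed master random seed; per-stage substreams are derived from
#'   it so the codeset, cohort draw and held-out null draws are
#'   independently reproducible.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_non = 9L, n_focal = 11L, n_ext = 25L,
                          n_endogenous = 740L, n_housekeeping = 30L,
                          n_positive = 6L, n_negative = 8L,
                          n_de_strong = 70L, n_de_moderate = 74L,
                          frac_de_down = 0.06,
                          baseline_log_mean = 7, baseline_log_sd = 1.5,
                          hk_log_mean = 10, hk_log_sd = 0.5,
                          nb_dispersion = 0.05, lane_factor_sd = 0.3,
                          background_mean = 10,
                          nerve_fraction_range = c(0.005, 0.80),
                          seed = 1L) {
  cfg <- list(n_non = n_non, n_focal = n_focal, n_ext = n_ext,
              n_endogenous = n_endogenous, n_housekeeping = n_housekeeping,
              n_positive = n_positive, n_negative = n_negative,
              n_de_strong = n_de_strong, n_de_moderate = n_de_moderate,
              frac_de_down = frac_de_down,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              hk_log_mean = hk_log_mean, hk_log_sd = hk_log_sd,
              nb_dispersion = nb_dispersion, lane_factor_sd = lane_factor_sd,
              background_mean = background_mean,
              nerve_fraction_range = nerve_fraction_range, seed = seed)
  counts <- c("n_non", "n_focal", "n_ext", "n_endogenous", "n_housekeeping",
              "n_positive", "n_negative", "n_de_strong", "n_de_moderate")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("invalid config: '", f, "' must be a single nonnegative integer")
  }
  if (cfg$n_de_strong + cfg$n_de_moderate > cfg$n_endogenous)
    stop("invalid config: 'n_de_strong' + 'n_de_moderate' exceeds 'n_endogenous'")
  if (cfg$frac_de_down < 0 || cfg$frac_de_down > 1)
    stop("invalid config: 'frac_de_down' must lie in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("invalid config: 'nb_dispersion' must be >= 0")
  if (cfg$lane_factor_sd < 0) stop("invalid config: 'lane_factor_sd' must be >= 0")
  if (cfg$background_mean < 0) stop("invalid config: 'background_mean' must be >= 0")
  if (length(cfg$nerve_fraction_range) != 2L ||
      any(cfg$nerve_fraction_range < 0) || any(cfg$nerve_fraction_range > 1) ||
      diff(cfg$nerve_fraction_range) < 0)
    stop("invalid config: 'nerve_fraction_range' must be an increasing interval in [0, 1]")
  class(cfg) <- "cohort_config"
  cfg
}

# Per-stage RNG substreams derived from the master seed, so that e.g. the
# held-out null draw does not perturb the cohort draw.
stage_seed <- function(seed, stage) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  s[[match(stage, c("codeset", "cohort", "null", "clinical", "extra1", "extra2"))]]
}

# The codeset is a deterministic function of the master seed: probe ids,
# per-gene baselines, planted-effect assignment and the positive-control
# ladder. Sharing it between generate_cohort() and generate_null_samples()
# keeps held-out samples on the same probe distribution.
build_codeset <- function(config) {
  set.seed(stage_seed(config$seed, "codeset"))
  endo_ids <- sprintf("GENE%04d", seq_len(config$n_endogenous))
  hk_ids <- sprintf("HK%02d", seq_len(config$n_housekeeping))
  pos_ids <- paste0("POS_", LETTERS[seq_len(config$n_positive)])
  neg_ids <- paste0("NEG_", LETTERS[seq_len(config$n_negative)])
  baseline <- c(
    stats::rnorm(config$n_endogenous, config$baseline_log_mean, config$baseline_log_sd),
    stats::rnorm(config$n_housekeeping, config$hk_log_mean, config$hk_log_sd))
  names(baseline) <- c(endo_ids, hk_ids)
  n_de <- config$n_de_strong + config$n_de_moderate
  de_ids <- if (n_de > 0) sample(endo_ids, n_de) else character(0)
  lfc <- rep(c(2.0, 1.3), c(config$n_de_strong, config$n_de_moderate))
  n_down <- round(config$frac_de_down * n_de)
  if (n_down > 0) {
    down <- sample.int(n_de, n_down)
    lfc[down] <- -lfc[down]
  }
  names(lfc) <- de_ids
  # nCounter-style geometric positive-control ladder (4-fold dilutions),
  # scaled per lane by the lane factor.
  ladder <- 32768 / 4^(seq_len(config$n_positive) - 1L)
  names(ladder) <- pos_ids
  list(endo_ids = endo_ids, hk_ids = hk_ids, pos_ids = pos_ids,
       neg_ids = neg_ids, baseline = baseline, de_lfc = lfc, ladder = ladder)
}

# Draw counts for a set of samples. `lfc_cols` marks samples carrying the
# planted effects (EXT); all technical layers apply to every sample.
draw_counts <- function(config, codeset, sample_names, lfc_cols, lane) {
  ns <- length(sample_names)
  mu_sig <- outer(2^codeset$baseline, lane)
  if (length(codeset$de_lfc) && any(lfc_cols)) {
    idx <- match(names(codeset$de_lfc), names(codeset$baseline))
    mu_sig[idx, lfc_cols] <- mu_sig[idx, lfc_cols] * 2^codeset$de_lfc
  }
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  sig <- if (is.finite(size))
    matrix(stats::rnbinom(length(mu_sig), mu = mu_sig, size = size), nrow(mu_sig))
  else
    matrix(stats::rpois(length(mu_sig), mu_sig), nrow(mu_sig))
  pos <- matrix(stats::rpois(config$n_positive * ns, outer(codeset$ladder, lane)),
                config$n_positive)
  bg_rows <- nrow(sig) + config$n_positive
  bg <- matrix(stats::rpois(bg_rows * ns, config$background_mean), bg_rows)
  neg <- matrix(stats::rpois(config$n_negative * ns, config$background_mean),
                config$n_negative)
  values <- rbind(sig + bg[seq_len(nrow(sig)), , drop = FALSE],
                  pos + bg[nrow(sig) + seq_len(config$n_positive), , drop = FALSE],
                  neg)
  storage.mode(values) <- "integer"
  rownames(values) <- c(codeset$endo_ids, codeset$hk_ids, codeset$pos_ids, codeset$neg_ids)
  colnames(values) <- sample_names
  cls <- rep(PROBE_CLASSES, c(config$n_endogenous, config$n_housekeeping,
                              config$n_positive, config$n_negative))
  nanoset(values, cls)
}

#' Generate a synthetic PNI cohort with known ground truth
#'
#' Draws one full cohort under the configured study conditions. Planted
#' fold changes apply only to EXT samples; Focal and Non samples come from
#' the same distribution; housekeeping and control probes carry no cohort
#' effect; every sample's signal is scaled by its lane factor before the
#' Poisson background is added; the nerve-fraction covariate is sampled
#' independently of expression. Two calls with the same config are
#' identical.
#'
#' @param config a [cohort_config()].
#' @return list of class `pni_cohort` with elements `counts` (a
#'   [nanoset()] of raw integer counts), `annotation` (sample table with
#'   cohort label, nerve fraction and clinical covariates) and `truth`
#'   (planted DE gene ids with signed log2 fold changes, per-sample lane
#'   factors, cohort labels).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  codeset <- build_codeset(config)
  set.seed(stage_seed(config$seed, "cohort"))
  n <- c(config$n_non, config$n_focal, config$n_ext)
  cohort <- rep(c("NON", "FOCAL", "EXT"), n)
  ids <- c(sprintf("NON-%d", seq_len(n[1])), sprintf("FOCAL-%d", seq_len(n[2])),
           sprintf("EXT-%d", seq_len(n[3])))
  lane <- exp(stats::rnorm(sum(n), 0, config$lane_factor_sd))
  names(lane) <- ids
  counts <- draw_counts(config, codeset, ids, cohort == "EXT", lane)
  nerve <- stats::runif(sum(n), config$nerve_fraction_range[1], config$nerve_fraction_range[2])
  set.seed(stage_seed(config$seed, "clinical"))
  recur_rate <- c(NON = 3 / 9, FOCAL = 3 / 11, EXT = 14 / 25)[cohort]
  annotation <- data.frame(
    sample_id = ids,
    cohort = factor(cohort, levels = c("NON", "FOCAL", "EXT")),
    nerve_fraction = nerve,
    age = round(stats::rnorm(sum(n), 70, 9), 1),
    sex = sample(c("F", "M"), sum(n), replace = TRUE, prob = c(0.13, 0.87)),
    tumor_width_mm = round(pmax(stats::rnorm(sum(n), 33, 12), 5)),
    tumor_thickness_mm = round(pmax(stats::rnorm(sum(n), 11, 5), 1)),
    recurrence = stats::rbinom(sum(n), 1L, recur_rate) == 1L,
    stringsAsFactors = FALSE)
  truth <- list(de_gene_ids = names(codeset$de_lfc),
                true_log2fc = codeset$de_lfc,
                lane_factors = lane,
                cohort_labels = stats::setNames(cohort, ids))
  structure(list(counts = counts, annotation = annotation, truth = truth),
            class = "pni_cohort")
}

#' @export
print.pni_cohort <- function(x, ...) {
  cat("<pni_cohort>\n")
  print(x$counts)
  cat("  cohorts:", paste(sprintf("%s=%d", names(table(x$annotation$cohort)),
                                  table(x$annotation$cohort)), collapse = ", "), "\n")
  cat(sprintf("  planted DE genes: %d\n", length(x$truth$de_gene_ids)))
  invisible(x)
}

#' Draw held-out samples from the null (Non/Focal) distribution
#'
#' Produces additional samples on the same codeset as [generate_cohort()]
#' with the same config, carrying no planted effects — the held-out
#' controls used for score-calibration experiments.
#'
#' @param config a [cohort_config()].
#' @param n number of samples; `n = 0` returns an empty matrix with the
#'   full probe index.
#' @param prefix sample-id prefix (default `"NULL"`).
#' @return a [nanoset()] of raw counts with `n` columns.
#' @export
generate_null_samples <- function(config = cohort_config(), n, prefix = "NULL") {
  stopifnot(inherits(config, "cohort_config"))
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("'n' must be a single nonnegative integer")
  codeset <- build_codeset(config)
  set.seed(stage_seed(config$seed, "null"))
  ids <- if (n > 0) sprintf("%s-%d", prefix, seq_len(n)) else character(0)
  if (n == 0) {
    values <- matrix(integer(0), nrow = with(config, n_endogenous + n_housekeeping +
                                               n_positive + n_negative), ncol = 0,
                     dimnames = list(c(codeset$endo_ids, codeset$hk_ids,
                                       codeset$pos_ids, codeset$neg_ids),
                                     character(0)))
    cls <- rep(PROBE_CLASSES, c(config$n_endogenous, config$n_housekeeping,
                                config$n_positive, config$n_negative))
    return(nanoset(values, cls))
  }
  lane <- exp(stats::rnorm(n, 0, config$lane_factor_sd))
  names(lane) <- ids
  draw_counts(config, codeset, ids, rep(FALSE, n), lane)
}
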