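#' Pearson chi-square test on a contingency table
#'
#' All-zero rows and columns are dropped before testing; the statistic is
#' the usual `sum((O - E)^2 / E)` with expectations from the margins, no
#' continuity correction by default. A flag reports expected counts
#' below 5.
#'
#' @param tab matrix or table of nonnegative integer counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `df`, `p_value`, `expected` and
#'   `low_expected` (any expected count < 5).
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table after dropping all-zero rows/columns")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected,
       low_expected = any(res$expected < 5))
}

#' Two-sample t-test on a continuous covariate
#'
#' Pooled-variance Student t by default, Welch optional.
#'
#' @param values_a,values_b numeric vectors, each with >= 2 values.
#' @param equal_variance pooled-variance Student t when TRUE (default);
#'   FALSE gives Welch.
#' @return list with `t`, `df`, `p_value` and the group means.
#' @export
two_sample_t <- function(values_a, values_b, equal_variance = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs >= 2 values")
  res <- stats::t.test(values_a, values_b, var.equal = equal_variance)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Cohort comparison summary (Table-1 style)
#'
#' Compares clinical covariates between EXT and the remaining samples
#' (Non and Focal combined by default, mirroring the study's pooled
#' analysis; `combine = FALSE` keeps the three cohorts as separate
#' columns). Continuous covariates use the two-sample t-test, categorical
#' covariates the chi-square test.
#'
#' @param annotation a [sample_annotation()] data.frame.
#' @param continuous,categorical column names to test; defaults cover the
#'   generated clinical covariates that are present.
#' @param combine combine NON and FOCAL into one comparison group
#'   (default TRUE).
#' @return data.frame with one row per covariate: test, statistic, df,
#'   p_value.
#' @export
cohort_stat_table <- function(annotation,
                              continuous = c("age", "tumor_width_mm",
                                             "tumor_thickness_mm", "nerve_fraction"),
                              categorical = c("sex", "recurrence"),
                              combine = TRUE) {
  annotation <- sample_annotation(annotation)
  grp <- if (combine) factor(ifelse(annotation$cohort == "EXT", "EXT", "FOCAL_NON"),
                             levels = c("FOCAL_NON", "EXT"))
         else annotation$cohort
  rows <- list()
  for (v in intersect(continuous, names(annotation))) {
    if (combine) {
      r <- two_sample_t(annotation[[v]][grp == "FOCAL_NON"],
                        annotation[[v]][grp == "EXT"])
      rows[[v]] <- data.frame(covariate = v, test = "t", statistic = r$t,
                              df = r$df, p_value = r$p_value,
                              stringsAsFactors = FALSE)
    } else {
      r <- stats::oneway.test(annotation[[v]] ~ grp, var.equal = TRUE)
      rows[[v]] <- data.frame(covariate = v, test = "anova",
                              statistic = unname(r$statistic),
                              df = unname(r$parameter[1L]),
                              p_value = unname(r$p.value),
                              stringsAsFactors = FALSE)
    }
  }
  for (v in intersect(categorical, names(annotation))) {
    tab <- table(annotation[[v]], grp)
    r <- tryCatch(chi_square_test(tab),
                  error = function(e) list(statistic = NA_real_, df = NA_real_,
                                           p_value = NA_real_))
    rows[[v]] <- data.frame(covariate = v, test = "chi-square",
                            statistic = r$statistic, df = r$df,
                            p_value = r$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
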