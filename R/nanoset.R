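#' Probe-class-aware expression matrix
#'
#' A `nanoset` couples a probes x samples numeric matrix with the NanoString
#' probe class of each row (`Endogenous`, `Housekeeping`, `Positive`,
#' `Negative`). It is the container every pipeline stage consumes and
#' returns; raw matrices hold nonnegative integer counts, normalized
#' matrices hold nonnegative reals.
#'
#' @param values numeric matrix, probes in rows (unique rownames required),
#'   samples in columns (unique colnames required); all values nonnegative.
#' @param probe_class character vector, one class token per row. Tokens are
#'   matched case-insensitively and canonicalized.
#' @return An object of class `nanoset`.
#' @export
nanoset <- function(values, probe_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || (ncol(values) > 0L && is.null(colnames(values))))
    stop("'values' must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ", colnames(values)[duplicated(colnames(values))][1L])
  if (length(probe_class) != nrow(values))
    stop("'probe_class' length must equal the number of probe rows")
  probe_class <- canonical_probe_class(probe_class)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and nonnegative")
  structure(list(values = values, probe_class = probe_class), class = "nanoset")
}

PROBE_CLASSES <- c("Endogenous", "Housekeeping", "Positive", "Negative")

canonical_probe_class <- function(x) {
  idx <- match(tolower(x), tolower(PROBE_CLASSES))
  if (anyNA(idx)) stop("unknown probe class token: ", x[is.na(idx)][1L])
  factor(PROBE_CLASSES[idx], levels = PROBE_CLASSES)
}

#' @export
dim.nanoset <- function(x) dim(x$values)

#' Accessors for `nanoset` objects
#'
#' @param x a [nanoset()].
#' @param class optional probe class; restricts the returned probes.
#' @return `probe_ids`/`sample_ids` return character vectors; `probe_class`
#'   the per-probe class factor; `ns_values` the numeric matrix (optionally
#'   restricted to one probe class).
#' @export
probe_ids <- function(x, class = NULL) {
  if (is.null(class)) rownames(x$values)
  else rownames(x$values)[x$probe_class == class]
}

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname probe_ids
#' @export
probe_class <- function(x) x$probe_class

#' @rdname probe_ids
#' @export
ns_values <- function(x, class = NULL) {
  if (is.null(class)) x$values
  else x$values[x$probe_class == class, , drop = FALSE]
}

#' Subset a nanoset by probes and/or samples
#'
#' @param x a [nanoset()].
#' @param probes,samples character, logical or integer row/column indexers;
#'   `NULL` keeps everything.
#' @return a [nanoset()].
#' @export
ns_subset <- function(x, probes = NULL, samples = NULL) {
  v <- x$values
  cls <- x$probe_class
  if (!is.null(probes)) {
    i <- if (is.character(probes)) match(probes, rownames(v)) else seq_len(nrow(v))[probes]
    if (anyNA(i)) stop("unknown probe id: ", probes[is.na(i)][1L])
    v <- v[i, , drop = FALSE]
    cls <- cls[i]
  }
  if (!is.null(samples)) {
    j <- if (is.character(samples)) match(samples, colnames(v)) else seq_len(ncol(v))[samples]
    if (anyNA(j)) stop("unknown sample id: ", samples[is.na(j)][1L])
    v <- v[, j, drop = FALSE]
  }
  structure(list(values = v, probe_class = cls), class = "nanoset")
}

#' Replace the value matrix of a nanoset, keeping probe metadata
#' @noRd
ns_replace_values <- function(x, values) {
  stopifnot(identical(dim(values), dim(x$values)))
  x$values <- values
  x
}

#' @export
print.nanoset <- function(x, ...) {
  cat(sprintf("<nanoset> %d probes x %d samples\n", nrow(x$values), ncol(x$values)))
  tab <- table(x$probe_class)
  cat("  probes: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  cat("  samples:", paste(utils::head(colnames(x$values), 4L), collapse = ", "),
      if (ncol(x$values) > 4L) "..." else "", "\n")
  invisible(x)
}

#' Validate a sample annotation table
#'
#' Checks the contract every analysis stage assumes: one row per sample, a
#' cohort label in `NON`, `FOCAL`, `EXT`, and a nerve-tissue fraction in
#' `[0, 1]`. Extra clinical columns are carried through untouched.
#'
#' @param annotation data.frame with at least `sample_id`, `cohort`,
#'   `nerve_fraction`.
#' @param x optional [nanoset()]; if given, every sample column must have
#'   exactly one annotation row.
#' @return the validated data.frame (cohort as factor `NON`/`FOCAL`/`EXT`).
#' @export
sample_annotation <- function(annotation, x = NULL) {
  need <- c("sample_id", "cohort", "nerve_fraction")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$sample_id))
    stop("duplicate annotation row for sample: ",
         annotation$sample_id[duplicated(annotation$sample_id)][1L])
  lv <- c("NON", "FOCAL", "EXT")
  if (!all(annotation$cohort %in% lv))
    stop("cohort labels must be one of NON, FOCAL, EXT")
  annotation$cohort <- factor(as.character(annotation$cohort), levels = lv)
  nf <- annotation$nerve_fraction
  if (any(!is.na(nf) & (nf < 0 | nf > 1)))
    stop("nerve_fraction must lie in [0, 1]")
  if (!is.null(x)) {
    missing_ann <- setdiff(sample_ids(x), annotation$sample_id)
    if (length(missing_ann))
      stop("samples without annotation: ", paste(missing_ann, collapse = ", "))
  }
  annotation
}
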