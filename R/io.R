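#' Read a probe count/expression table
#'
#' Tab-separated layout: first column probe id, second column probe class
#' (`Endogenous`, `Housekeeping`, `Positive`, `Negative`; matched
#' case-insensitively), remaining columns one per sample. Malformed input
#' is rejected, never coerced: duplicate probe ids, unknown class tokens,
#' ragged rows and negative or non-numeric values all raise errors.
#'
#' @param path file path.
#' @return a [nanoset()].
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("counts table has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(fields)
  if (any(width != width[1L]))
    stop("ragged row at line ", which(width != width[1L])[1L], " in ", path)
  header <- fields[[1L]]
  if (width[1L] < 3L) stop("counts table needs probe id, probe class and >= 1 sample column")
  body <- do.call(rbind, fields[-1L])
  ids <- body[, 1L]
  if (anyDuplicated(ids)) stop("duplicate probe id: ", ids[duplicated(ids)][1L])
  cls <- canonical_probe_class(body[, 2L])
  values <- suppressWarnings(matrix(as.numeric(body[, -(1:2), drop = FALSE]),
                                    nrow = nrow(body)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at line ", bad[1L] + 1L, ", column ", header[bad[2L] + 2L])
  }
  dimnames(values) <- list(ids, header[-(1:2)])
  nanoset(values, as.character(cls))
}

#' Write a probe count/expression table
#'
#' Inverse of [read_counts_table()]; integer matrices round-trip
#' bit-exactly, real matrices are written at full precision.
#'
#' @param x a [nanoset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(x, path) {
  v <- ns_values(x)
  txt <- if (is.integer(v) || all(v == round(v))) format(v, scientific = FALSE, trim = TRUE)
         else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  out <- cbind(probe_id = rownames(v), probe_class = as.character(probe_class(x)), txt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample annotation tables (CSV)
#'
#' @param path file path.
#' @return `read_annotation` returns a validated [sample_annotation()]
#'   data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sample_annotation(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_annotation
#' @param annotation a [sample_annotation()] data.frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read NanoString RCC lane files
#'
#' Minimal RCC dialect: plain-text files with `<Header>`,
#' `<Sample_Attributes>`, `<Lane_Attributes>` and `<Code_Summary>`
#' sections; the `Code_Summary` section holds `CodeClass,Name,Accession,
#' Count` rows. One sample column is produced per file; the sample id is
#' taken from the `ID` row of `Sample_Attributes`, falling back to the
#' file name. All lanes must share one probe set.
#'
#' @param paths character vector of RCC file paths.
#' @return a [nanoset()] with one column per lane.
#' @export
read_rcc <- function(paths) {
  if (!length(paths)) stop("no RCC files given")
  lanes <- lapply(paths, read_rcc_one)
  ref <- lanes[[1L]]
  for (ln in lanes[-1L]) {
    if (!identical(rownames(ref$values), rownames(ln$values))) {
      miss <- union(setdiff(rownames(ref$values), rownames(ln$values)),
                    setdiff(rownames(ln$values), rownames(ref$values)))
      stop("inconsistent probe sets across lanes; differing probes: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
  }
  values <- do.call(cbind, lapply(lanes, `[[`, "values"))
  colnames(values) <- vapply(lanes, `[[`, "", "sample_id")
  nanoset(values, as.character(lanes[[1L]]$class))
}

read_rcc_one <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  sect <- function(name) {
    a <- match(paste0("<", name, ">"), lines)
    b <- match(paste0("</", name, ">"), lines)
    if (is.na(a) || is.na(b) || b <= a) return(NULL)
    lines[(a + 1L):(b - 1L)]
  }
  code <- sect("Code_Summary")
  if (is.null(code)) stop("missing Code_Summary section in ", path)
  rows <- strsplit(code, ",", fixed = TRUE)
  header <- rows[[1L]]
  if (!identical(header[1:4], c("CodeClass", "Name", "Accession", "Count")))
    stop("unexpected Code_Summary header in ", path)
  body <- do.call(rbind, rows[-1L])
  cnt <- suppressWarnings(as.numeric(body[, 4L]))
  if (anyNA(cnt)) stop("non-numeric count in Code_Summary of ", path)
  if (any(cnt < 0)) stop("negative count in Code_Summary of ", path)
  sample_id <- basename(sub("\\.[Rr][Cc][Cc]$", "", path))
  attrs <- sect("Sample_Attributes")
  if (!is.null(attrs)) {
    kv <- strsplit(attrs, ",", fixed = TRUE)
    id_row <- Filter(function(x) identical(x[1L], "ID"), kv)
    if (length(id_row) && nzchar(id_row[[1L]][2L])) sample_id <- id_row[[1L]][2L]
  }
  values <- matrix(cnt, ncol = 1L, dimnames = list(body[, 2L], sample_id))
  list(values = values, class = canonical_probe_class(body[, 1L]), sample_id = sample_id)
}

#' Write one minimal RCC lane file per sample
#'
#' @param x a [nanoset()] of raw integer counts.
#' @param dir output directory (created if needed).
#' @return the written file paths, invisibly.
#' @export
write_rcc <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- ns_values(x)
  paths <- file.path(dir, paste0(colnames(v), ".RCC"))
  for (j in seq_len(ncol(v))) {
    con <- file(paths[j], "w")
    writeLines(c("<Header>", "FileVersion,1.7", "SoftwareVersion,pniscore", "</Header>",
                 "<Sample_Attributes>", paste0("ID,", colnames(v)[j]), "</Sample_Attributes>",
                 "<Lane_Attributes>", paste0("ID,", j), "</Lane_Attributes>",
                 "<Code_Summary>", "CodeClass,Name,Accession,Count",
                 sprintf("%s,%s,NA,%d", as.character(probe_class(x)), rownames(v),
                         as.integer(v[, j])),
                 "</Code_Summary>"), con)
    close(con)
  }
  invisible(paths)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set id, description, then member gene symbols.
#' Duplicate members within one set are collapsed; an empty file yields an
#' empty collection; a line with fewer than three fields is an error.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (set id -> members) with a
#'   `set_name` attribute carrying the descriptions.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- list()
    attr(out, "set_name") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop("GMT line ", short[1L], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate gene-set id: ", ids[duplicated(ids)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "set_name") <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  sets
}
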