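#' @importFrom rlang %||% .data
#' @importFrom stats median setNames sd var
#' @importFrom utils head combn
NULL

# canonical encodings accepted for a SNP call
.normalize_snp_calls <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("a", "anc", "ancestral", "0", "-")] <- "ancestral"
  out[x %in% c("d", "der", "derived", "1", "+")] <- "derived"
  bad <- !is.na(x) & x != "" & x != "na" & is.na(out)
  if (any(bad)) {
    stop("unrecognized SNP call value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected ancestral/derived/A/D/0/1 or missing)", call. = FALSE)
  }
  out
}

#' Read a per-sample genotype table
#'
#' Reads a TSV/CSV table with one row per man: identifier and group labels,
#' repeat counts for the STR loci of `panel`, and (optionally) SNP marker
#' columns coded ancestral/derived. The result is the tidy sample table
#' every downstream function consumes.
#'
#' DYS389 handling: assays report DYS389II as a total that physically
#' includes DYS389I. With `dys389_format = "total"` the table carries a
#' `DYS389II` column and the independent repeat count is derived as
#' `DYS389b = DYS389II - DYS389I`; with `"separate"` the table already
#' carries `DYS389b`.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` file with a header.
#'   Required columns: `sample_id`, `population`; optional `clan`.
#' @param panel A [ystr_panel()]; defaults to the 17-locus Y-filer panel.
#' @param snp_markers Character vector of SNP marker names to look for as
#'   columns; defaults to the 35-marker backbone plus the C2*-ST downstream
#'   set.
#' @param dys389_format `"separate"` (default) or `"total"`, see above.
#' @return A tibble with columns `sample_id`, `population`, `clan`, one
#'   integer column per panel locus and one character column
#'   (ancestral/derived/NA) per SNP marker found, with the panel attached
#'   as attribute `"panel"`.
#' @export
read_samples <- function(path, panel = yfiler17_panel(),
                         snp_markers = c(snp_backbone_markers(),
                                         c2st_downstream_markers()),
                         dys389_format = c("separate", "total")) {
  dys389_format <- match.arg(dys389_format)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
  for (col in c("sample_id", "population")) {
    if (!col %in% names(raw)) stop("missing required column: ", col, call. = FALSE)
  }
  if (!"clan" %in% names(raw)) raw$clan <- NA_character_

  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup)) stop("duplicated sample ID(s): ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)

  want_loci <- panel$loci
  if (dys389_format == "total") {
    if (!"DYS389II" %in% names(raw))
      stop("dys389_format = \"total\" but no DYS389II column", call. = FALSE)
    want_loci <- setdiff(want_loci, "DYS389b")
    want_loci <- union(want_loci, c("DYS389I", "DYS389II"))
  }

  miss <- setdiff(want_loci, names(raw))
  if (length(miss)) stop("missing STR locus column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  # columns that look like STR loci but are not in the configured panel
  strish <- grepl("^(DYS|GATA|Y_?GATA)", names(raw), ignore.case = FALSE)
  unknown <- setdiff(names(raw)[strish], c(want_loci, panel$loci))
  if (length(unknown)) stop("unknown STR locus column(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)

  parse_int <- function(col) {
    x <- raw[[col]]
    v <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & (is.na(v) | v != as.numeric(x)))
    if (length(bad)) {
      stop(sprintf("non-integer repeat value %s in column %s, row %d",
                   x[bad[1]], col, bad[1]), call. = FALSE)
    }
    neg <- which(!is.na(v) & v <= 0)
    if (length(neg)) {
      stop(sprintf("non-positive repeat value in column %s, row %d",
                   col, neg[1]), call. = FALSE)
    }
    v
  }
  str_cols <- lapply(setNames(want_loci, want_loci), parse_int)

  if (dys389_format == "total") {
    str_cols$DYS389b <- str_cols$DYS389II - str_cols$DYS389I
    str_cols$DYS389II <- NULL
  }
  str_tbl <- tibble::as_tibble(str_cols)[, panel$loci]

  snps <- intersect(snp_markers, names(raw))
  snp_tbl <- if (!length(snps)) tibble::tibble(.rows = nrow(raw)) else
    tibble::as_tibble(lapply(setNames(snps, snps), function(m) {
      tryCatch(.normalize_snp_calls(raw[[m]]),
               error = function(e) stop("column ", m, ": ", conditionMessage(e),
                                        call. = FALSE))
    }))

  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = raw$sample_id,
                   population = raw$population,
                   clan = raw$clan),
    str_tbl, snp_tbl
  )
  attr(out, "panel") <- panel
  message(sprintf("read %d samples (%d STR loci, %d SNP markers) from %s",
                  nrow(out), length(panel$loci), length(snps), path))
  out
}

#' Write a sample table
#'
#' Inverse of [read_samples()] for the `"separate"` DYS389 convention:
#' writes a TSV that [read_samples()] reads back to the identical table.
#'
#' @param data A sample table (tibble).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_samples <- function(data, path) {
  readr::write_tsv(data, path, na = "")
  invisible(path)
}

#' Write / read a machine-readable analysis report
#'
#' The report bundle is an arbitrarily nested named list of scalars,
#' vectors and data frames (frequency tables, cluster memberships, TMRCA
#' tables, F_ST values, ...). It is serialized as JSON with data frames
#' stored row-wise, so `read_report(write_report(x, p))` restores the
#' values exactly; a short human-readable summary of the top-level
#' sections goes to stderr.
#'
#' @param results Named list; may be empty.
#' @param path Output `.json` path.
#' @return `path` invisibly (`write_report`); the restored list
#'   (`read_report`).
#' @export
write_report <- function(results, path) {
  stopifnot(is.list(results))
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null",
                       pretty = TRUE)
  message(sprintf("report with %d section(s) [%s] -> %s",
                  length(results), paste(names(results), collapse = ", "), path))
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
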