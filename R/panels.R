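#' STR locus panels
#'
#' A locus panel is the ordered set of Y-STR loci a haplotype is scored on.
#' The standard forensic Y-filer panel has 17 loci, two of which
#' (DYS385a/b) are a multi-copy pair whose alleles cannot be assigned to a
#' specific copy; network and dating analyses therefore run on the 15
#' single-copy loci. DYS389 is special: assays report DYS389I and DYS389II,
#' where DYS389II physically contains DYS389I, so the independent quantity
#' is DYS389b = DYS389II - DYS389I. Panels here always store DYS389b.
#'
#' @param loci Character vector of locus names (unique, ordered).
#' @param multi_copy Subset of `loci` flagged as multi-copy; these are
#'   dropped by [network_panel()].
#' @return An object of class `locus_panel`: a list with elements `loci`
#'   and `multi_copy`.
#' @examples
#' p <- yfiler17_panel()
#' length(p$loci)           # 17
#' length(network_panel(p)$loci)  # 15
#' @export
ystr_panel <- function(loci, multi_copy = character()) {
  stopifnot(is.character(loci), !anyDuplicated(loci))
  if (!all(multi_copy %in% loci)) {
    stop("multi_copy loci not in panel: ",
         paste(setdiff(multi_copy, loci), collapse = ", "))
  }
  structure(list(loci = loci, multi_copy = multi_copy),
            class = "locus_panel")
}

#' @rdname ystr_panel
#' @export
yfiler17_panel <- function() {
  ystr_panel(
    c("DYS19", "DYS389I", "DYS389b", "DYS390", "DYS391", "DYS392",
      "DYS393", "DYS385a", "DYS385b", "DYS437", "DYS438", "DYS439",
      "DYS448", "DYS456", "DYS458", "DYS635", "GATA_H4"),
    multi_copy = c("DYS385a", "DYS385b")
  )
}

#' @rdname ystr_panel
#' @param panel A `locus_panel`.
#' @export
network_panel <- function(panel = yfiler17_panel()) {
  ystr_panel(setdiff(panel$loci, panel$multi_copy))
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("<locus_panel> ", length(x$loci), " loci", sep = "")
  if (length(x$multi_copy))
    cat(" (multi-copy: ", paste(x$multi_copy, collapse = ", "), ")", sep = "")
  cat("\n", paste(x$loci, collapse = " "), "\n", sep = "")
  invisible(x)
}

# internal: resolve the panel for a sample table, preferring the attribute
# stamped by read_samples()/simulate_*().
.get_panel <- function(data, panel = NULL) {
  panel %||% attr(data, "panel") %||% yfiler17_panel()
}

.assert_panel_cols <- function(data, panel) {
  miss <- setdiff(panel$loci, names(data))
  if (length(miss))
    stop("sample table is missing STR locus columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# haplotype matrix (samples x loci) from a sample table
.hap_matrix <- function(data, panel) {
  .assert_panel_cols(data, panel)
  m <- as.matrix(data[, panel$loci, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- data$sample_id
  m
}
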