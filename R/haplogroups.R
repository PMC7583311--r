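#' Assign a haplogroup from SNP calls
#'
#' Walks the haplogroup tree from the root and returns the deepest node
#' whose defining marker is called derived with every marker on the path
#' above it also derived. Missing calls are untested: the walk cannot
#' extend through them, so partial genotyping yields the deepest
#' *confirmed* clade. The returned label is annotated with the daughter
#' clades that were tested and found ancestral — `"C2-M217(xM48, M407)"`
#' style with `annotate = "xlist"`, or a trailing `*` (paragroup style,
#' `"F5481*"`) with `annotate = "star"`. A derived call whose parent
#' marker is called ancestral is an inconsistency and raises an error
#' naming both markers.
#'
#' @param calls Named character vector of calls
#'   (`"ancestral"`/`"derived"`/`NA`), names = marker names; markers absent
#'   from the tree are ignored.
#' @param tree A [read_haplogroup_tree()] tree.
#' @param annotate `"xlist"`, `"star"`, or `"none"`.
#' @param root_label Label returned when no marker is derived.
#' @return A single haplogroup label string.
#' @examples
#' tr <- snp_backbone_tree()
#' assign_haplogroup(
#'   c(M130 = "derived", M217 = "derived", M48 = "ancestral",
#'     M407 = "ancestral"), tr)   # "C2-M217(xM48, M407)"
#' @export
assign_haplogroup <- function(calls, tree, annotate = c("xlist", "star", "none"),
                              root_label = "Y*") {
  annotate <- match.arg(annotate)
  calls <- calls[!is.na(names(calls)) & names(calls) %in% tree$marker]
  calls <- calls[!is.na(calls)]
  parent_of <- setNames(tree$parent, tree$marker)
  depth_of <- setNames(tree$depth, tree$marker)
  label_of <- setNames(tree$haplogroup, tree$marker)

  der <- names(calls)[calls == "derived"]
  # consistency: a derived marker under an ancestral parent is impossible
  for (m in der) {
    p <- parent_of[[m]]
    if (p != "ROOT" && !is.na(calls[p] %||% NA) && identical(unname(calls[p]), "ancestral"))
      stop(sprintf("inconsistent SNP calls: %s is derived but its parent %s is ancestral",
                   m, p), call. = FALSE)
  }
  # a node counts only if its whole ancestor chain is called derived
  confirmed <- der[vapply(der, function(m) {
    cur <- parent_of[[m]]
    while (cur != "ROOT") {
      if (!cur %in% der) return(FALSE)
      cur <- parent_of[[cur]]
    }
    TRUE
  }, logical(1))]

  if (!length(confirmed)) return(root_label)
  best <- confirmed[order(-depth_of[confirmed], confirmed)][1]

  label <- label_of[[best]]
  if (annotate != "none") {
    daughters <- tree$marker[tree$parent == best]
    neg <- daughters[daughters %in% names(calls) & calls[daughters] == "ancestral"]
    if (length(neg)) {
      label <- if (annotate == "xlist")
        paste0(label, "(x", paste(neg, collapse = ", "), ")")
      else paste0(label, "*")
    }
  }
  unname(label)
}

#' Assign haplogroups to every sample in a table
#'
#' @param data Sample table with SNP marker columns (see [read_samples()]).
#' @param tree Haplogroup tree; defaults to the 35-marker backbone.
#' @param column Name of the output column.
#' @inheritParams assign_haplogroup
#' @return `data` with the assignment column added (tibble).
#' @export
assign_haplogroups <- function(data, tree = snp_backbone_tree(),
                               column = "haplogroup",
                               annotate = "xlist", root_label = "Y*") {
  markers <- intersect(tree$marker, names(data))
  if (!length(markers))
    stop("no SNP marker columns of this tree found in the table", call. = FALSE)
  m <- as.matrix(data[, markers, drop = FALSE])
  labels <- vapply(seq_len(nrow(m)), function(i) {
    assign_haplogroup(setNames(m[i, ], markers), tree,
                      annotate = annotate, root_label = root_label)
  }, character(1))
  data[[column]] <- labels
  message(sprintf("assigned %s for %d samples (%d distinct labels)",
                  column, nrow(data), dplyr::n_distinct(labels)))
  data
}

#' Downstream C2*-ST subclade assignment
#'
#' Same tree walk as [assign_haplogroups()], run on the F3796/F8951
#' downstream marker set with paragroup-style annotation, so an
#' F5481-derived sample with all tested daughter branches ancestral is
#' reported as `"F5481*"`.
#'
#' @inheritParams assign_haplogroups
#' @export
assign_c2_downstream <- function(data, tree = c2st_tree(),
                                 column = "c2_subclade") {
  out <- assign_haplogroups(data, tree, column = column,
                            annotate = "star", root_label = NA_character_)
  # leave untyped samples unassigned: the downstream panel is only run on
  # the C2*-ST subset, so a sample with no downstream call gets NA rather
  # than the backbone root of the subtree
  down <- intersect(setdiff(tree$marker, tree$marker[tree$parent == "ROOT"]),
                    names(data))
  if (length(down)) {
    typed <- rowSums(!is.na(as.matrix(data[, down, drop = FALSE]))) > 0
    out[[column]][!typed] <- NA_character_
  }
  out
}

#' C2*-ST STR motif classification
#'
#' When downstream SNPs are unavailable, membership in the C2*-ST (Star
#' Cluster) lineage is called from the 15-locus STR haplotype: a sample is
#' classified C2*-ST when its step distance to the motif's reference modal
#' haplotype is at most `max_steps`. The shipped centroid is an *assumed*
#' modal haplotype (the defining motif is not part of the package's
#' marker assays), kept in `inst/extdata/c2st_motif.tsv`; both it and the
#' threshold are configuration, not constants.
#'
#' @param centroid Named integer vector over the 15 single-copy loci, or
#'   `NULL` for the shipped default.
#' @param max_steps Non-negative integer step threshold (default 5).
#' @param label Motif label.
#' @return `c2st_motif()`: a list of class `str_motif`.
#' @export
c2st_motif <- function(centroid = NULL, max_steps = 5, label = "C2*-ST") {
  if (is.null(centroid)) {
    tab <- readr::read_tsv(system.file("extdata", "c2st_motif.tsv",
                                       package = "ystrnet", mustWork = TRUE),
                           col_types = "ci", progress = FALSE)
    centroid <- setNames(as.integer(tab$repeats), tab$locus)
  }
  stopifnot(max_steps >= 0, !is.null(names(centroid)))
  structure(list(centroid = centroid, max_steps = as.integer(max_steps),
                 label = label), class = "str_motif")
}

#' @rdname c2st_motif
#' @param h Named integer vector: one haplotype on the motif's loci.
#' @param motif A [c2st_motif()].
#' @return `classify_c2st_by_str()`: `TRUE`/`FALSE`.
#' @export
classify_c2st_by_str <- function(h, motif = c2st_motif()) {
  loci <- names(motif$centroid)
  if (!all(loci %in% names(h)))
    stop("haplotype is missing motif loci: ",
         paste(setdiff(loci, names(h)), collapse = ", "), call. = FALSE)
  h <- h[loci]
  if (anyNA(h))
    stop("STR-motif classification needs a complete haplotype; missing: ",
         paste(loci[is.na(h)], collapse = ", "), call. = FALSE)
  step_distance(h, motif$centroid) <= motif$max_steps
}

#' @rdname c2st_motif
#' @param data Sample table.
#' @param column Output logical column name.
#' @return `classify_c2st()`: `data` with the logical column added;
#'   samples with missing motif loci get `NA`.
#' @export
classify_c2st <- function(data, motif = c2st_motif(), column = "c2st_str") {
  loci <- names(motif$centroid)
  .assert_panel_cols(data, ystr_panel(loci))
  m <- as.matrix(data[, loci, drop = FALSE])
  data[[column]] <- vapply(seq_len(nrow(m)), function(i) {
    if (anyNA(m[i, ])) return(NA)
    classify_c2st_by_str(setNames(m[i, ], loci), motif)
  }, logical(1))
  data
}

#' Haplogroup frequency profiles
#'
#' Counts and relative frequencies of haplogroups per group (clan or
#' population). Rows of the frequency matrix sum to 1.
#'
#' @param data Sample table with a haplogroup column.
#' @param group Grouping column name: `"clan"` or `"population"`.
#' @param haplogroup Haplogroup column name.
#' @return A tibble of class `hg_freq` with columns `group`, `haplogroup`,
#'   `n`, `freq`, plus attributes `group_sizes` and `n_haplogroups`.
#' @export
hg_frequencies <- function(data, group = c("clan", "population"),
                           haplogroup = "haplogroup") {
  group <- match.arg(group)
  if (!haplogroup %in% names(data))
    stop("no '", haplogroup, "' column; run assign_haplogroups() first",
         call. = FALSE)
  keep <- !is.na(data[[group]])
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) without a ", group,
            " label omitted from the frequency table", call. = FALSE)
    data <- data[keep, ]
  }
  out <- data |>
    dplyr::count(group = .data[[group]], haplogroup = .data[[haplogroup]],
                 name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, dplyr::desc(.data$freq), .data$haplogroup)
  attr(out, "group_sizes") <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$n)) |>
    tibble::deframe()
  attr(out, "n_haplogroups") <- dplyr::n_distinct(out$haplogroup)
  class(out) <- c("hg_freq", class(out))
  out
}

# group x haplogroup matrices from an hg_freq table
.freq_matrix <- function(f, value = c("freq", "n")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(f[, c("group", "haplogroup", value)],
                             names_from = "haplogroup",
                             values_from = dplyr::all_of(value),
                             values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$group
  m[, order(colnames(m)), drop = FALSE]
}

#' @rdname hg_frequencies
#' @param object An `hg_freq` table.
#' @param ... Unused.
#' @method glance hg_freq
#' @export
glance.hg_freq <- function(object, ...) {
  tibble::tibble(n_groups = dplyr::n_distinct(object$group),
                 n_haplogroups = attr(object, "n_haplogroups"),
                 n_samples = sum(object$n))
}

#' Stacked-bar haplogroup frequency plot
#'
#' @param object An `hg_freq` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hg_freq
#' @export
autoplot.hg_freq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$freq,
                                       fill = .data$haplogroup)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = NULL, y = "frequency", fill = "haplogroup") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
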