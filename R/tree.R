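#' Haplogroup trees
#'
#' A haplogroup tree maps each haplogroup label to its defining SNP marker
#' and its parent, as a `(haplogroup, marker, parent)` table where `parent`
#' is the parent node's marker, or `"ROOT"` for top-level clades hanging
#' off the (markerless) Y root. The shipped backbone tree covers the
#' 35-marker genotyping panel with an ISOGG-style topology; the C2*-ST
#' subtree covers the downstream F3796/F8951 markers. Both are plain TSV
#' configuration files under `inst/extdata`, validated on load: marker
#' names must be unique, every parent must exist, and the structure must
#' be a single rooted acyclic tree.
#'
#' @param path TSV file with columns `haplogroup`, `marker`, `parent`.
#' @return A tibble of class `haplogroup_tree` with columns `haplogroup`,
#'   `marker`, `parent`, `depth` (root children have depth 1).
#' @export
read_haplogroup_tree <- function(path) {
  tr <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  stopifnot(all(c("haplogroup", "marker", "parent") %in% names(tr)))
  if (anyDuplicated(tr$marker))
    stop("duplicated defining marker(s): ",
         paste(unique(tr$marker[duplicated(tr$marker)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tr$haplogroup))
    stop("duplicated haplogroup label(s) in tree", call. = FALSE)
  unknown <- setdiff(tr$parent, c("ROOT", tr$marker))
  if (length(unknown))
    stop("parent marker(s) not defined in tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!any(tr$parent == "ROOT"))
    stop("tree has no root-level clade", call. = FALSE)

  # depth by walking up; also detects cycles
  depth <- setNames(rep(NA_integer_, nrow(tr)), tr$marker)
  parent_of <- setNames(tr$parent, tr$marker)
  for (m in tr$marker) {
    d <- 0L; cur <- m; seen <- character()
    while (cur != "ROOT") {
      if (cur %in% seen) stop("cycle in tree at marker ", cur, call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
      d <- d + 1L
    }
    depth[[m]] <- d
  }
  tr$depth <- unname(depth[tr$marker])
  class(tr) <- c("haplogroup_tree", class(tr))
  tr
}

#' @rdname read_haplogroup_tree
#' @export
snp_backbone_tree <- function() {
  read_haplogroup_tree(system.file("extdata", "snp_tree_35.tsv",
                                   package = "ystrnet", mustWork = TRUE))
}

#' @rdname read_haplogroup_tree
#' @export
c2st_tree <- function() {
  read_haplogroup_tree(system.file("extdata", "c2st_tree.tsv",
                                   package = "ystrnet", mustWork = TRUE))
}

#' @rdname read_haplogroup_tree
#' @export
snp_backbone_markers <- function() snp_backbone_tree()$marker

#' @rdname read_haplogroup_tree
#' @export
c2st_downstream_markers <- function() setdiff(c2st_tree()$marker, "M217")

# markers on the path from the root down to (and including) `marker`
.tree_path <- function(tree, marker) {
  parent_of <- setNames(tree$parent, tree$marker)
  if (!marker %in% tree$marker) stop("marker not in tree: ", marker, call. = FALSE)
  path <- character()
  cur <- marker
  while (cur != "ROOT") {
    path <- c(cur, path)
    cur <- parent_of[[cur]]
  }
  path
}
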