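#' Mutational step distance between STR haplotypes
#'
#' Under single-step mutation, the minimum number of mutations separating
#' two haplotypes is the sum over loci of absolute repeat-count
#' differences (weighted Manhattan distance when per-locus weights are
#' supplied). This is the metric in which networks are built and cluster
#' ages are measured.
#'
#' @param a,b Integer vectors of repeat counts on the same locus panel
#'   (no missing values). If both are named, `b` is aligned to `a`'s names.
#' @param weights Optional positive per-locus weights (default: all 1).
#' @return Non-negative number (an integer count for unit weights).
#' @examples
#' step_distance(c(13, 29, 24), c(14, 28, 24))  # 2
#' @export
step_distance <- function(a, b, weights = NULL) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("locus panels differ", call. = FALSE)
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("locus panels differ (unequal length)", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing repeat counts", call. = FALSE)
  w <- weights %||% rep(1, length(a))
  sum(w * abs(as.numeric(a) - as.numeric(b)))
}

# pairwise weighted-Manhattan distance matrix for a haplotype matrix
.step_dist_matrix <- function(H, weights = NULL) {
  if (!is.null(weights)) H <- sweep(H, 2, weights, `*`)
  as.matrix(stats::dist(H, method = "manhattan"))
}
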