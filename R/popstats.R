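#' Haplotype diversity
#'
#' Nei's unbiased gene (haplotype) diversity:
#' `HD = n/(n-1) * (1 - sum_i p_i^2)`, the small-sample-corrected
#' probability that two randomly drawn haplotypes differ.
#'
#' @param data Sample table (haplotypes taken over `panel`'s loci), or a
#'   vector of pre-computed haplotype keys via `haplotype_diversity(keys)`.
#' @param panel Locus panel (default: single-copy network panel).
#' @return A number in `[0, 1]`.
#' @export
haplotype_diversity <- function(data, panel = NULL) {
  key <- if (is.data.frame(data)) {
    panel <- panel %||% network_panel(.get_panel(data))
    H <- .hap_matrix(data, panel)
    H <- H[stats::complete.cases(H), , drop = FALSE]
    apply(H, 1, paste, collapse = ",")
  } else {
    as.character(data)
  }
  n <- length(key)
  if (n < 2) stop("haplotype diversity needs at least 2 samples", call. = FALSE)
  p <- as.numeric(table(key)) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' One-level AMOVA F_ST
#'
#' Analysis of molecular variance over a partition of samples into units,
#' with pairwise distance `delta = 0/1` haplogroup mismatch (default) or
#' squared STR step distance. Sums of squares follow the standard
#' decomposition: `SSD(total) = (1/2N) * sum_ij delta_ij`,
#' `SSD(within) = sum_g (1/2n_g) * sum_{ij in g} delta_ij`,
#' variance components `sigma2_w = SSD(within)/(N-G)`,
#' `sigma2_a = (SSD(among)/(G-1) - sigma2_w)/n'` with
#' `n' = (N - sum n_g^2/N)/(G-1)`, and `F_ST =
#' sigma2_a / (sigma2_a + sigma2_w)`.
#'
#' @param data Sample table with haplogroups assigned (or STR columns for
#'   `distance = "str_steps"`).
#' @param units Either the name of a grouping column, or a named vector
#'   mapping values of `group_col` to unit labels (merged grouping
#'   schemes, e.g. several clans pooled into one "core" unit).
#' @param group_col Column the `units` mapping applies to (default
#'   `"clan"`).
#' @param distance `"haplogroup"` (0/1 mismatch) or `"str_steps"`
#'   (squared step distance on the network panel).
#' @param haplogroup Haplogroup column name.
#' @param panel Locus panel for `"str_steps"`.
#' @return Object of class `ystr_amova`: list with `fst`, `components`
#'   (tibble: source, df, SS, variance), `scheme`, `n`, `n_units`.
#' @export
amova_fst <- function(data, units, group_col = "clan",
                      distance = c("haplogroup", "str_steps"),
                      haplogroup = "haplogroup", panel = NULL) {
  distance <- match.arg(distance)
  if (length(units) == 1 && is.null(names(units))) {
    unit <- data[[units]]
    scheme <- units
  } else {
    unit <- unname(units[data[[group_col]]])
    scheme <- paste0(length(unique(stats::na.omit(units))), "-unit scheme")
  }
  keep <- !is.na(unit)
  data <- data[keep, ]; unit <- unit[keep]
  N <- nrow(data)
  G <- dplyr::n_distinct(unit)
  if (G < 2) stop("AMOVA needs at least 2 units", call. = FALSE)
  if (min(table(unit)) < 1) stop("empty unit", call. = FALSE)

  delta2 <- if (distance == "haplogroup") {
    if (!haplogroup %in% names(data))
      stop("no '", haplogroup, "' column; run assign_haplogroups() first",
           call. = FALSE)
    hg <- data[[haplogroup]]
    outer(hg, hg, FUN = `!=`) * 1
  } else {
    panel <- panel %||% network_panel(.get_panel(data))
    .step_dist_matrix(.hap_matrix(data, panel))^2
  }

  ssd_total <- sum(delta2) / (2 * N)
  ng <- table(unit)
  ssd_within <- sum(vapply(names(ng), function(g) {
    idx <- which(unit == g)
    sum(delta2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within

  df_a <- G - 1
  df_w <- N - G
  sigma2_w <- ssd_within / df_w
  n_prime <- (N - sum(ng^2) / N) / df_a
  sigma2_a <- (ssd_among / df_a - sigma2_w) / n_prime
  # negative variance-component estimates are truncated at zero for F_ST
  # (the raw component is kept in the table)
  fst <- if (sigma2_a <= 0) 0 else sigma2_a / (sigma2_a + sigma2_w)

  structure(list(
    fst = fst,
    components = tibble::tibble(
      source = c("among units", "within units"),
      df = c(df_a, df_w),
      SS = c(ssd_among, ssd_within),
      variance = c(sigma2_a, sigma2_w)
    ),
    scheme = scheme, distance = distance, n = N, n_units = G
  ), class = "ystr_amova")
}

#' @export
print.ystr_amova <- function(x, ...) {
  cat(sprintf("<ystr_amova> %s, %d samples in %d units: F_ST = %.4f\n",
              x$scheme, x$n, x$n_units, x$fst))
  print(x$components)
  invisible(x)
}

#' @rdname amova_fst
#' @param x,object A `ystr_amova`.
#' @param ... Unused.
#' @method tidy ystr_amova
#' @export
tidy.ystr_amova <- function(x, ...) x$components

#' @rdname amova_fst
#' @method glance ystr_amova
#' @export
glance.ystr_amova <- function(x, ...) {
  tibble::tibble(fst = x$fst, n = x$n, n_units = x$n_units,
                 scheme = x$scheme, distance = x$distance)
}

#' Nei's standard genetic distance between groups
#'
#' `D(x, y) = -ln( sum_i x_i y_i / sqrt(sum_i x_i^2 * sum_i y_i^2) )` over
#' haplogroup frequency vectors. Pairs sharing no haplogroup have
#' identity 0 and distance `Inf`, reported as such.
#'
#' @param f An [hg_frequencies()] table or a group-by-category frequency
#'   matrix with row names.
#' @return Symmetric matrix of class `nei_dist` with zero diagonal.
#' @export
nei_distance <- function(f) {
  m <- if (inherits(f, "hg_freq")) .freq_matrix(f) else as.matrix(f)
  xx <- rowSums(m^2)
  num <- m %*% t(m)
  I <- num / sqrt(outer(xx, xx))
  D <- -log(I)
  D[I <= 0] <- Inf
  diag(D) <- 0
  D <- (D + t(D)) / 2   # enforce exact symmetry against rounding
  class(D) <- c("nei_dist", class(D))
  D
}

#' Ordination of clan profiles
#'
#' Deterministic ordinations of the group profiles: classical metric MDS
#' (Torgerson double-centering) of a distance matrix, PCA of the centered
#' frequency matrix, or Ward (ward.D2) hierarchical clustering of a
#' distance matrix.
#'
#' @param x A distance matrix (`mds`, `ward`) or frequency table/matrix
#'   (`pca`).
#' @param method `"mds"`, `"pca"` or `"ward"`.
#' @param dims Number of output dimensions for `mds`/`pca`.
#' @return For `mds`/`pca`: tibble of class `ystr_ordination` with
#'   `group`, `axis1`, `axis2`, ... and an attribute `"diagnostics"`
#'   (explained variance / eigenvalue share per axis). For `ward`: the
#'   `hclust` object.
#' @export
ordinate <- function(x, method = c("mds", "pca", "ward"), dims = 2) {
  method <- match.arg(method)
  if (method == "pca") {
    m <- if (inherits(x, "hg_freq")) .freq_matrix(x) else as.matrix(x)
    p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    k <- min(dims, ncol(p$x))
    coords <- p$x[, seq_len(k), drop = FALSE]
    diag_ <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  } else {
    m <- as.matrix(x)
    if (!isSymmetric(unname(m), tol = 1e-8))
      stop("distance matrix must be symmetric", call. = FALSE)
    if (method == "ward") {
      hc <- stats::hclust(stats::as.dist(m), method = "ward.D2")
      return(hc)
    }
    md <- suppressWarnings(stats::cmdscale(stats::as.dist(m),
                                           k = min(dims, nrow(m) - 1),
                                           eig = TRUE))
    coords <- md$points
    # degenerate (flat) geometries come back with fewer columns; pad with 0
    if (ncol(coords) < dims)
      coords <- cbind(coords, matrix(0, nrow(m), dims - ncol(coords)))
    pos <- md$eig[md$eig > 1e-12]
    diag_ <- if (length(pos)) (pmax(md$eig, 0) / sum(pos))[seq_len(ncol(coords))]
             else rep(0, ncol(coords))
  }
  out <- tibble::as_tibble(coords, .name_repair = ~ paste0("axis", seq_along(.x)))
  out <- dplyr::bind_cols(tibble::tibble(group = rownames(m)), out)
  attr(out, "diagnostics") <- diag_
  attr(out, "method") <- method
  class(out) <- c("ystr_ordination", class(out))
  out
}

#' @rdname ordinate
#' @param object A `ystr_ordination`.
#' @param ... Unused.
#' @method autoplot ystr_ordination
#' @export
autoplot.ystr_ordination <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                       label = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(x = "axis 1", y = "axis 2",
                  title = toupper(attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' Export a Ward dendrogram as Newick
#'
#' @param hc An `hclust` object (from `ordinate(..., "ward")`).
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
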