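#' Dating parameters
#'
#' Calibration for converting mutational distance to years: per-locus
#' mutation rate `mu` (mutations per STR locus per generation, default
#' 2.1e-3), number of loci `n_loci` (default 15), generation time
#' `gen_years` (years, default 30), and the normal CI multiplier `z`
#' (default 1.96 for 95%).
#'
#' @param mu,n_loci,gen_years,z Positive numbers.
#' @return A list of class `dating_params`.
#' @export
dating_params <- function(mu = 2.1e-3, n_loci = 15, gen_years = 30, z = 1.96) {
  stopifnot(mu > 0, n_loci > 0, gen_years > 0, z > 0)
  structure(list(mu = mu, n_loci = n_loci, gen_years = gen_years, z = z),
            class = "dating_params")
}

#' Rho statistic: mean mutational distance to the founder
#'
#' `rho = (1/n) * sum_i d(h_i, founder)`, where each sampled chromosome
#' counts once and distances are measured along network geodesics (in
#' mutational steps) from the founder node.
#'
#' @param net An `mj_network`.
#' @param members Data frame with columns `sample_id` and `node` (e.g. the
#'   rows of one cluster from [extract_clusters()]).
#' @param founder Founder node name.
#' @return The rho value (non-negative number).
#' @export
rho_statistic <- function(net, members, founder) {
  stopifnot(inherits(net, "mj_network"), founder %in% net$nodes$node)
  dm <- igraph::distances(net$graph, v = founder, to = unique(members$node),
                          weights = igraph::E(net$graph)$weight)
  d <- setNames(dm[1, ], colnames(dm))
  if (any(!is.finite(d)))
    stop("cluster member(s) disconnected from founder: ",
         paste(names(d)[!is.finite(d)], collapse = ", "), call. = FALSE)
  mean(d[members$node])
}

#' Standard error of rho over a rooted genealogy
#'
#' `sigma^2 = (1/n^2) * sum_e l_e * n_e^2`, summing over genealogy edges,
#' where `l_e` is the mutational length of edge `e` and `n_e` the number
#' of sampled chromosomes whose path to the founder passes through it.
#' For a star genealogy this reduces to `sigma^2 = rho / n`.
#'
#' @param edges Data frame with columns `parent`, `child`, `length`
#'   describing a tree rooted at the founder.
#' @param members Character vector of node names, one entry per sampled
#'   chromosome (repeat a node for multiplicity).
#' @return The sigma value.
#' @export
sigma_rho <- function(edges, members) {
  stopifnot(all(c("parent", "child", "length") %in% names(edges)))
  parent_of <- setNames(edges$parent, edges$child)
  roots <- setdiff(edges$parent, edges$child)
  if (length(unique(roots)) != 1)
    stop("genealogy must be a single rooted tree (found ",
         length(unique(roots)), " roots)", call. = FALSE)
  root <- unique(roots)
  n_e <- setNames(rep(0, nrow(edges)), edges$child)
  for (v in members) {
    cur <- v
    while (cur != root) {
      if (!cur %in% names(parent_of))
        stop("member node not in genealogy: ", v, call. = FALSE)
      n_e[cur] <- n_e[cur] + 1
      cur <- parent_of[[cur]]
    }
  }
  n <- length(members)
  sqrt(sum(edges$length * n_e[edges$child]^2) / n^2)
}

#' Shortest-path genealogy of a cluster within a network
#'
#' Builds the genealogy used for the rho variance: the shortest-path tree
#' from the founder to the member nodes inside the network (deterministic
#' given the network's canonical node order).
#'
#' @inheritParams rho_statistic
#' @return Data frame of tree edges (`parent`, `child`, `length`).
#' @export
cluster_genealogy <- function(net, members, founder) {
  nodes <- setdiff(unique(members$node), founder)
  if (!length(nodes))
    return(tibble::tibble(parent = character(), child = character(),
                          length = numeric()))
  sp <- igraph::shortest_paths(net$graph, from = founder, to = nodes,
                               weights = igraph::E(net$graph)$weight,
                               output = "vpath")
  W <- .step_dist_matrix(net$H, net$weights)
  seen <- character()
  out <- list()
  for (p in sp$vpath) {
    nm <- names(p)
    if (length(nm) < 2) next
    for (k in 2:length(nm)) {
      if (nm[k] %in% seen) next
      seen <- c(seen, nm[k])
      out[[length(out) + 1L]] <- tibble::tibble(
        parent = nm[k - 1], child = nm[k], length = W[nm[k - 1], nm[k]])
    }
  }
  dplyr::bind_rows(out)
}

#' Convert rho to a TMRCA estimate in years
#'
#' `age = gen_years * rho / (n_loci * mu)`; the 95% CI applies the same
#' conversion to `rho +/- z * sigma`, with the lower bound clamped at 0.
#'
#' @param rho,sigma Rho value and its standard error.
#' @param n Number of sampled chromosomes behind `rho`.
#' @param params A [dating_params()].
#' @return One-row tibble of class `tmrca_estimate`: `n`, `rho`, `sigma`,
#'   `age_years`, `ci_low_years`, `ci_high_years`.
#' @examples
#' tmrca(rho = 1, sigma = 0.5, n = 4)  # ~952 years, CI [19, 1886]
#' @export
tmrca <- function(rho, sigma, n = NA_integer_, params = dating_params()) {
  stopifnot(inherits(params, "dating_params"), rho >= 0, sigma >= 0)
  scale <- params$gen_years / (params$n_loci * params$mu)
  out <- tibble::tibble(
    n = n, rho = rho, sigma = sigma,
    age_years = scale * rho,
    ci_low_years = max(0, scale * (rho - params$z * sigma)),
    ci_high_years = scale * (rho + params$z * sigma)
  )
  attr(out, "params") <- params
  class(out) <- c("tmrca_estimate", class(out))
  out
}

#' Date the clusters of a network
#'
#' For each cluster: pick the founder (the member node with the highest
#' multiplicity, ties lexicographic, unless overridden), compute rho along
#' network geodesics, its standard error over the shortest-path genealogy,
#' and convert to years.
#'
#' @param net An `mj_network`.
#' @param clusters A [extract_clusters()] result.
#' @param founders Optional named character vector `cluster -> node`.
#' @param params A [dating_params()].
#' @return Tibble of class `tmrca_estimate`, one row per cluster with
#'   `cluster`, `founder`, `n`, `rho`, `sigma`, `age_years`,
#'   `ci_low_years`, `ci_high_years`.
#' @export
date_clusters <- function(net, clusters, founders = NULL,
                          params = dating_params()) {
  mult <- setNames(net$nodes$multiplicity, net$nodes$node)
  rows <- lapply(sort(unique(clusters$cluster)), function(cl) {
    mem <- clusters[clusters$cluster == cl, ]
    founder <- if (!is.null(founders) && cl %in% names(founders)) {
      founders[[cl]]
    } else {
      nds <- unique(mem$node)
      nds[order(-mult[nds], nds)][1]
    }
    rho <- rho_statistic(net, mem, founder)
    gen <- cluster_genealogy(net, mem, founder)
    sig <- if (nrow(gen)) sigma_rho(gen, mem$node) else 0
    est <- tmrca(rho, sig, n = nrow(mem), params = params)
    dplyr::bind_cols(tibble::tibble(cluster = cl, founder = founder), est)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- params
  class(out) <- c("tmrca_estimate", class(out))
  out
}

#' Star dating of a haplotype table
#'
#' Direct (non-network) rho dating of a set of haplotypes against a
#' founder haplotype: rho is the mean step distance to the founder, and
#' the variance uses the star closed form `sigma^2 = rho / n` (each
#' sampled chromosome on its own branch). The default founder is the
#' modal (most frequent) haplotype, ties broken lexicographically.
#'
#' @param data Sample table.
#' @param founder Named integer founder haplotype, or `NULL` for modal.
#' @param panel Network locus panel.
#' @param params A [dating_params()].
#' @return One-row [tmrca()] tibble.
#' @export
rho_tmrca <- function(data, founder = NULL, panel = NULL,
                      params = dating_params()) {
  panel <- panel %||% network_panel(.get_panel(data))
  H <- .hap_matrix(data, panel)
  H <- H[stats::complete.cases(H), , drop = FALSE]
  if (!nrow(H)) stop("no complete haplotypes", call. = FALSE)
  if (is.null(founder)) {
    key <- apply(H, 1, paste, collapse = ",")
    tb <- table(key)
    modal_key <- names(tb)[order(-tb, names(tb))][1]
    founder <- H[match(modal_key, key), ]
  } else {
    founder <- founder[panel$loci]
  }
  d <- colSums(abs(t(H) - as.numeric(founder)))
  rho <- mean(d)
  n <- nrow(H)
  tmrca(rho, sqrt(rho / n), n = n, params = params)
}

#' @rdname tmrca
#' @param x A `tmrca_estimate`.
#' @param ... Unused.
#' @method tidy tmrca_estimate
#' @export
tidy.tmrca_estimate <- function(x, ...) {
  tibble::as_tibble(x)
}
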