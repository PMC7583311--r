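# ---- internal graph primitives -------------------------------------------
# Kruskal MST on a dense symmetric distance matrix. Deterministic: edges
# sorted by (weight, i, j). Returns list(edges = matrix[i, j, w], cost).
.kruskal_mst <- function(D) {
  m <- nrow(D)
  if (m == 1) return(list(edges = matrix(numeric(0), 0, 3,
                                         dimnames = list(NULL, c("i", "j", "w"))),
                          cost = 0))
  ut <- which(upper.tri(D))
  i <- ((ut - 1) %% m) + 1
  j <- ((ut - 1) %/% m) + 1
  w <- D[ut]
  ord <- order(w, i, j)
  i <- i[ord]; j <- j[ord]; w <- w[ord]
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- logical(length(w)); n_edge <- 0L
  for (e in seq_along(w)) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) {
      parent[ri] <- rj
      keep[e] <- TRUE
      n_edge <- n_edge + 1L
      if (n_edge == m - 1L) break
    }
  }
  edges <- cbind(i = i[keep], j = j[keep], w = w[keep])
  list(edges = edges, cost = sum(edges[, "w"]))
}

# minimax (maximum edge weight along the unique MST path) for all pairs
.minimax_matrix <- function(mst_edges, m) {
  adj <- vector("list", m)
  for (e in seq_len(nrow(mst_edges))) {
    i <- mst_edges[e, "i"]; j <- mst_edges[e, "j"]; w <- mst_edges[e, "w"]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  mm <- matrix(Inf, m, m); diag(mm) <- 0
  for (s in seq_len(m)) {        # DFS from s over the tree
    stack <- s; visited <- logical(m); visited[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (!visited[u]) {
          visited[u] <- TRUE
          mm[s, u] <- max(mm[s, v], nb[r, 2])
          stack <- c(stack, u)
        }
      }
    }
    mm[s, s] <- 0
  }
  mm
}

# epsilon-relaxed minimum spanning network: all links (u,v) with
# d(u,v) <= minimax(u,v) + epsilon. epsilon = 0 gives the union of all MSTs.
.msn_edges <- function(D, epsilon = 0) {
  m <- nrow(D)
  mst <- .kruskal_mst(D)
  if (m < 2) return(mst$edges)
  mm <- .minimax_matrix(mst$edges, m)
  ut <- which(upper.tri(D) & D <= mm + epsilon + 1e-9)
  i <- ((ut - 1) %% m) + 1
  j <- ((ut - 1) %/% m) + 1
  cbind(i = i, j = j, w = D[ut])
}

# ---- condensation --------------------------------------------------------

#' Condense a sample table to unique haplotypes
#'
#' Groups samples carrying an identical haplotype on the network panel
#' into one condensed node with a multiplicity, the carrier IDs, and the
#' clan/population composition. Samples missing any network-panel locus
#' are excluded (and reported), since step distances are undefined for
#' them.
#'
#' @param data Sample table.
#' @param panel Locus panel for the network; defaults to the single-copy
#'   subset of the table's panel.
#' @param label Column used for the composition mix (`"clan"` or
#'   `"population"`).
#' @return Tibble of class `condensed_haps` with columns `hap_id`,
#'   `multiplicity`, `carriers` (list), `label_mix` (character), ordered
#'   lexicographically by repeat vector; the haplotype matrix is attached
#'   as attribute `"H"`, excluded sample IDs as attribute `"excluded"`.
#' @export
condense_haplotypes <- function(data, panel = NULL, label = "population") {
  panel <- panel %||% network_panel(.get_panel(data))
  H <- .hap_matrix(data, panel)
  complete <- stats::complete.cases(H)
  if (any(!complete)) {
    message(sprintf("excluding %d sample(s) with missing network loci: %s",
                    sum(!complete),
                    paste(head(data$sample_id[!complete], 10), collapse = ", ")))
  }
  excluded <- data$sample_id[!complete]
  data <- data[complete, ]
  H <- H[complete, , drop = FALSE]
  if (!nrow(H)) stop("no samples with complete network haplotypes", call. = FALSE)

  key <- apply(H, 1, paste, collapse = ",")
  ord <- order(key)             # canonical (lexicographic) haplotype order
  ukey <- unique(key[ord])
  idx <- split(seq_len(nrow(H)), factor(key, levels = ukey))
  Hu <- H[vapply(idx, `[`, integer(1), 1), , drop = FALSE]
  hap_id <- sprintf("H%03d", seq_along(idx))
  rownames(Hu) <- hap_id
  labels <- if (label %in% names(data)) data[[label]] else rep(NA_character_, nrow(data))
  out <- tibble::tibble(
    hap_id = hap_id,
    multiplicity = lengths(idx),
    carriers = lapply(idx, function(k) data$sample_id[k]),
    label_mix = vapply(idx, function(k) {
      tb <- sort(table(labels[k]), decreasing = TRUE)
      paste(sprintf("%s:%d", names(tb), tb), collapse = ";")
    }, character(1))
  )
  attr(out, "H") <- Hu
  attr(out, "panel") <- panel
  attr(out, "excluded") <- excluded
  class(out) <- c("condensed_haps", class(out))
  out
}

# ---- median-joining construction -----------------------------------------

#' Build a median-joining network of STR haplotypes
#'
#' Implements the median-joining construction over condensed haplotypes:
#' (i) the epsilon-relaxed minimum spanning network links every pair of
#' nodes whose distance does not exceed the largest edge on their minimum
#' spanning tree path by more than `epsilon`; (ii) for every triplet with
#' at least two of its three pairs linked, the coordinate-wise median
#' vector is a candidate Steiner node scored by its connection cost
#' `d(u,m) + d(v,m) + d(w,m)`; each round adds every new median within
#' `epsilon` of the minimal connection cost, iterating to a fixpoint;
#' (iii) median vectors whose degree falls to 2 or below are pruned,
#' again to a fixpoint. Because every inserted median subdivides linked
#' geodesics, the total connection cost (MST length of the node set)
#' never increases across rounds; the per-round costs are kept in
#' `cost_trace`. Node processing follows the lexicographic order of
#' repeat vectors, so the network is deterministic for a given input.
#' Like all median-joining implementations this is a heuristic: it is not
#' guaranteed to reach the globally minimal Steiner network on
#' adversarial inputs, though it does on star-like configurations typical
#' of founder expansions.
#'
#' @param data Sample table or a [condense_haplotypes()] result.
#' @param panel Network locus panel (ignored when `data` is condensed).
#' @param epsilon Non-negative relaxation parameter (default 0, the usual
#'   software default).
#' @param weights Optional positive per-locus weights (default uniform).
#' @param label Composition column, see [condense_haplotypes()].
#' @param max_iter Safety cap on median insertions.
#' @return An object of class `mj_network`: list with the `igraph` graph,
#'   a `nodes` tibble (sampled flag, multiplicity, carriers, composition),
#'   the haplotype matrix `H` over all nodes, `cost` (MST length of the
#'   final node set), `epsilon`, `weights`, `n_samples`.
#' @export
build_mj_network <- function(data, panel = NULL, epsilon = 0, weights = NULL,
                             label = "population", max_iter = 200L) {
  stopifnot(epsilon >= 0)
  ch <- if (inherits(data, "condensed_haps")) data
        else condense_haplotypes(data, panel, label = label)
  panel <- attr(ch, "panel")
  Hs <- attr(ch, "H")
  n_loci <- ncol(Hs)
  if (!is.null(weights)) stopifnot(length(weights) == n_loci, all(weights > 0))

  H <- Hs
  sampled <- rep(TRUE, nrow(H))
  mv_count <- 0L
  cost_trace <- .kruskal_mst(.step_dist_matrix(H, weights))$cost

  repeat {
    D <- .step_dist_matrix(H, weights)
    m <- nrow(H)
    if (m < 3) break
    msn <- .msn_edges(D, epsilon)

    # candidate medians of triplets with at least two of their three pairs
    # linked in the MSN, scored by connection cost d(u,m)+d(v,m)+d(w,m)
    adj <- vector("list", m)
    for (e in seq_len(nrow(msn))) {
      adj[[msn[e, "i"]]] <- c(adj[[msn[e, "i"]]], msn[e, "j"])
      adj[[msn[e, "j"]]] <- c(adj[[msn[e, "j"]]], msn[e, "i"])
    }
    existing <- apply(H, 1, paste, collapse = ",")
    cand <- list()
    conn <- numeric()
    for (v in seq_len(m)) {
      nb <- sort(unique(adj[[v]]))
      if (length(nb) < 2) next
      prs <- combn(nb, 2)
      for (p in seq_len(ncol(prs))) {
        trip <- H[c(v, prs[1, p], prs[2, p]), , drop = FALSE]
        med <- apply(trip, 2, function(x) sort(x)[2])  # median of 3
        key <- paste(med, collapse = ",")
        if (key %in% existing) next
        cc <- sum(vapply(1:3, function(r)
          step_distance(trip[r, ], med, weights), numeric(1)))
        if (is.null(cand[[key]])) {
          cand[[key]] <- med
          conn[[key]] <- cc
        } else conn[[key]] <- min(conn[[key]], cc)
      }
    }
    if (!length(cand)) break
    lambda <- min(conn)
    add <- sort(names(conn)[conn <= lambda + epsilon + 1e-9])  # canonical order
    # keep a median only if the total connection cost (MST length of the
    # node set) does not increase, so the cost trace is monotone
    cur_cost <- cost_trace[length(cost_trace)]
    added <- FALSE
    for (key in add) {
      Hc <- rbind(H, cand[[key]])
      cost_c <- .kruskal_mst(.step_dist_matrix(Hc, weights))$cost
      if (cost_c <= cur_cost + 1e-9) {
        mv_count <- mv_count + 1L
        H <- Hc
        rownames(H)[nrow(H)] <- sprintf("MV%03d", mv_count)
        sampled <- c(sampled, FALSE)
        cur_cost <- cost_c
        added <- TRUE
      }
    }
    if (!added) break
    cost_trace <- c(cost_trace, cur_cost)
    if (mv_count >= max_iter) break
  }

  # prune median vectors of degree <= 2 to a fixpoint
  repeat {
    D <- .step_dist_matrix(H, weights)
    msn <- .msn_edges(D, epsilon)
    deg <- tabulate(c(msn[, "i"], msn[, "j"]), nbins = nrow(H))
    drop <- which(!sampled & deg <= 2)
    if (!length(drop)) break
    H <- H[-drop, , drop = FALSE]
    sampled <- sampled[-drop]
  }

  D <- .step_dist_matrix(H, weights)
  msn <- .msn_edges(D, epsilon)
  cost <- .kruskal_mst(D)$cost

  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(H)[msn[, "i"]],
               to = rownames(H)[msn[, "j"]],
               weight = msn[, "w"]),
    directed = FALSE,
    vertices = data.frame(name = rownames(H), sampled = sampled)
  )
  node_tbl <- tibble::tibble(node = rownames(H), sampled = sampled) |>
    dplyr::left_join(dplyr::rename(ch, node = "hap_id"), by = "node") |>
    dplyr::mutate(multiplicity = dplyr::coalesce(.data$multiplicity, 0L))

  structure(list(graph = g, nodes = node_tbl, H = H, cost = cost,
                 cost_trace = cost_trace,
                 epsilon = epsilon, weights = weights, panel = panel,
                 n_samples = sum(node_tbl$multiplicity),
                 excluded = attr(ch, "excluded")),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("<mj_network> %d nodes (%d sampled, %d median vectors), %d edges, cost %g, %d samples\n",
              nrow(x$H), sum(x$nodes$sampled), sum(!x$nodes$sampled),
              igraph::ecount(x$graph), x$cost, x$n_samples))
  invisible(x)
}

#' @rdname build_mj_network
#' @param x,object An `mj_network`.
#' @param ... Unused.
#' @method tidy mj_network
#' @export
tidy.mj_network <- function(x, ...) {
  x$nodes |>
    dplyr::mutate(degree = igraph::degree(x$graph)[.data$node])
}

#' @rdname build_mj_network
#' @method glance mj_network
#' @export
glance.mj_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$H),
                 n_sampled = sum(x$nodes$sampled),
                 n_median = sum(!x$nodes$sampled),
                 n_edges = igraph::ecount(x$graph),
                 cost = x$cost,
                 epsilon = x$epsilon,
                 n_samples = x$n_samples)
}

#' @rdname build_mj_network
#' @method autoplot mj_network
#' @export
autoplot.mj_network <- function(object, ...) {
  g <- object$graph
  xy <- igraph::layout_with_kk(g)
  nd <- tidy(object)
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  el <- igraph::as_edgelist(g)
  seg <- data.frame(x = nd$x[match(el[, 1], nd$node)],
                    y = nd$y[match(el[, 1], nd$node)],
                    xend = nd$x[match(el[, 2], nd$node)],
                    yend = nd$y[match(el[, 2], nd$node)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = pmax(.data$multiplicity, 0.5),
                                     colour = .data$sampled)) +
    ggplot2::scale_size_area(name = "carriers") +
    ggplot2::scale_colour_manual(values = c("TRUE" = "#2166AC", "FALSE" = "#B2182B"),
                                 labels = c("TRUE" = "sampled", "FALSE" = "median"),
                                 name = NULL) +
    ggplot2::theme_void()
}

#' Export a haplotype network
#'
#' Writes the network with node attributes (multiplicity, sampled flag,
#' composition) and edge weights in GraphML or GML.
#'
#' @param net An `mj_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"gml"`.
#' @export
write_network <- function(net, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- net$graph
  ord <- match(igraph::V(g)$name, net$nodes$node)
  igraph::V(g)$multiplicity <- net$nodes$multiplicity[ord]
  igraph::V(g)$label_mix <- dplyr::coalesce(net$nodes$label_mix[ord], "")
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

# ---- cluster extraction --------------------------------------------------

#' Extract founder clusters from a network
#'
#' Assigns every sampled haplotype to the nearest seed node by network
#' geodesic (in mutational steps). Ties go to the seed closer to the
#' global modal haplotype, then to the lexicographically first seed name.
#' With `k` instead of explicit seeds, the `k` highest-multiplicity nodes
#' are used (ties again lexicographic).
#'
#' @param net An `mj_network`.
#' @param seeds Character vector of node names, or `NULL` to use `k`.
#' @param k Number of automatic seeds.
#' @param cluster_names Optional names for the clusters (same length/order
#'   as the seeds); defaults to the seed node names.
#' @return Tibble of class `ystr_clusters`: `sample_id`, `node`,
#'   `cluster`; per-cluster summary (seed, size, composition) in attribute
#'   `"summary"`.
#' @export
extract_clusters <- function(net, seeds = NULL, k = NULL, cluster_names = NULL) {
  stopifnot(inherits(net, "mj_network"))
  nodes <- net$nodes
  if (is.null(seeds)) {
    if (is.null(k)) stop("supply either seeds or k", call. = FALSE)
    ord <- order(-nodes$multiplicity, nodes$node)
    seeds <- nodes$node[ord[seq_len(min(k, nrow(nodes)))]]
  }
  missing <- setdiff(seeds, nodes$node)
  if (length(missing)) stop("seed node(s) not in network: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  cluster_names <- cluster_names %||% seeds
  stopifnot(length(cluster_names) == length(seeds))

  dmat <- igraph::distances(net$graph, v = seeds,
                            weights = igraph::E(net$graph)$weight)
  modal <- nodes$node[order(-nodes$multiplicity, nodes$node)][1]
  d_seed_modal <- igraph::distances(net$graph, v = seeds, to = modal,
                                    weights = igraph::E(net$graph)$weight)[, 1]

  sampled <- nodes[nodes$sampled, ]
  assign_idx <- vapply(sampled$node, function(v) {
    d <- dmat[, v]
    cand <- which(d == min(d))
    if (length(cand) > 1) cand <- cand[order(d_seed_modal[cand], seeds[cand])]
    cand[1]
  }, integer(1))

  out <- tibble::tibble(
    sample_id = unlist(sampled$carriers),
    node = rep(sampled$node, lengths(sampled$carriers)),
    cluster = rep(cluster_names[assign_idx], lengths(sampled$carriers))
  )
  smry <- out |>
    dplyr::count(.data$cluster, name = "n") |>
    dplyr::left_join(tibble::tibble(cluster = cluster_names, seed = seeds),
                     by = "cluster")
  attr(out, "summary") <- smry
  attr(out, "seeds") <- setNames(seeds, cluster_names)
  class(out) <- c("ystr_clusters", class(out))
  out
}

# ---- jackknife stability -------------------------------------------------

#' Jackknife stability of network clusters
#'
#' Repeats the network construction and cluster extraction on datasets
#' with a fraction of the samples randomly omitted, and compares each
#' replicate clustering with the full-data clustering on the retained
#' samples: the adjusted Rand index, and per-cluster persistence (the
#' largest fraction of a full-data cluster's retained members that stay
#' together in one replicate cluster).
#'
#' @param data Sample table.
#' @param fraction Proportion omitted per replicate, in (0, 1); default
#'   0.10.
#' @param reps Number of replicates.
#' @param seed RNG seed.
#' @param k Number of automatic cluster seeds (passed to
#'   [extract_clusters()]).
#' @inheritParams build_mj_network
#' @return Tibble of class `jackknife_stability`: one row per replicate
#'   with `rep`, `ari`, `mean_persistence`, `min_persistence`; the
#'   full-data clustering is in attribute `"full"`.
#' @export
jackknife_stability <- function(data, fraction = 0.10, reps = 100, seed = 1,
                                k = 3, panel = NULL, epsilon = 0,
                                weights = NULL, label = "population") {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be in (0, 1)", call. = FALSE)
  stopifnot(reps >= 1)
  full_net <- build_mj_network(data, panel, epsilon, weights, label)
  full_cl <- extract_clusters(full_net, k = k)
  full_map <- setNames(full_cl$cluster, full_cl$sample_id)

  set.seed(seed)
  n <- nrow(data)
  n_drop <- max(1L, round(fraction * n))
  rows <- purrr::map(seq_len(reps), function(r) {
    keep <- sort(sample.int(n, n - n_drop))
    net_r <- suppressMessages(build_mj_network(data[keep, ], panel, epsilon,
                                               weights, label))
    cl_r <- extract_clusters(net_r, k = k)
    map_r <- setNames(cl_r$cluster, cl_r$sample_id)
    common <- intersect(names(full_map), names(map_r))
    a <- full_map[common]; b <- map_r[common]
    pers <- vapply(split(b, a), function(bb) max(table(bb)) / length(bb),
                   numeric(1))
    tibble::tibble(rep = r,
                   ari = mclust::adjustedRandIndex(a, b),
                   mean_persistence = mean(pers),
                   min_persistence = min(pers))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "full") <- full_cl
  class(out) <- c("jackknife_stability", class(out))
  message(sprintf("jackknife (%d reps, %.0f%% omitted): median ARI %.3f",
                  reps, 100 * fraction, median(out$ari)))
  out
}

#' @rdname jackknife_stability
#' @param object A `jackknife_stability` table.
#' @param ... Unused.
#' @method glance jackknife_stability
#' @export
glance.jackknife_stability <- function(object, ...) {
  tibble::tibble(reps = nrow(object),
                 median_ari = median(object$ari),
                 min_ari = min(object$ari),
                 mean_persistence = mean(object$mean_persistence))
}
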