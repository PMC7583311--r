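# Fixture builders and independent oracles used across the suite.

# wrap a haplotype matrix as a sample table on loci L1..Lk
as_hap_tbl <- function(H, clan = NA_character_, population = "pop",
                       ids = paste0("s", seq_len(nrow(H)))) {
  loci <- paste0("L", seq_len(ncol(H)))
  colnames(H) <- loci
  d <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids,
                   population = rep_len(population, nrow(H)),
                   clan = rep_len(clan, nrow(H))),
    tibble::as_tibble(H)
  )
  attr(d, "panel") <- ystr_panel(loci)
  d
}

toy_panel <- function(k) ystr_panel(paste0("L", seq_len(k)))

quiet_net <- function(H, ...) {
  suppressMessages(build_mj_network(as_hap_tbl(H), panel = toy_panel(ncol(H)), ...))
}

# --- independent MST / Steiner oracles (igraph-based, vs the package's own
# Kruskal implementation) ---------------------------------------------------

oracle_mst_cost <- function(H) {
  if (nrow(H) < 2) return(0)
  D <- as.matrix(stats::dist(H, method = "manhattan"))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# brute-force minimal-cost network: minimum over all subsets (up to n-2
# points) of the integer bounding-box lattice added as Steiner nodes
oracle_steiner_cost <- function(H, kmax = nrow(H) - 2) {
  rng <- apply(H, 2, range)
  grid <- as.matrix(expand.grid(lapply(seq_len(ncol(H)),
                                       function(j) rng[1, j]:rng[2, j])))
  keys <- apply(H, 1, paste, collapse = ",")
  gk <- apply(grid, 1, paste, collapse = ",")
  extra <- grid[!(gk %in% keys), , drop = FALSE]
  best <- oracle_mst_cost(H)
  if (nrow(extra) && kmax >= 1) {
    for (k in seq_len(min(kmax, nrow(extra)))) {
      if (choose(nrow(extra), k) > 50000) next
      cmb <- utils::combn(nrow(extra), k)
      for (cc in seq_len(ncol(cmb))) {
        best <- min(best, oracle_mst_cost(rbind(H, extra[cmb[, cc], , drop = FALSE])))
      }
    }
  }
  best
}

# star-like fixture: founder plus descendants a few +/-1 steps away (the
# geometry of an SMM founder expansion)
smm_star_fixture <- function(n, L = 3, max_steps = 3) {
  f <- rep(10L, L)
  H <- t(vapply(seq_len(n - 1), function(i) {
    h <- f
    for (s in seq_len(sample(seq_len(max_steps), 1))) {
      j <- sample(L, 1)
      h[j] <- h[j] + sample(c(-1L, 1L), 1)
    }
    h
  }, integer(L)))
  unique(rbind(f, H))
}

# --- sigma_rho oracle: sum over ordered member pairs of the shared
# root-path length (an algebraically equivalent but independent route) ----
oracle_sigma <- function(edges, members) {
  root <- setdiff(edges$parent, edges$child)
  path_edges <- function(v) {
    out <- character()
    while (v != root) {
      out <- c(out, v)
      v <- edges$parent[match(v, edges$child)]
    }
    out
  }
  len <- stats::setNames(edges$length, edges$child)
  paths <- lapply(members, path_edges)
  n <- length(members)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    tot <- tot + sum(len[shared])
  }
  sqrt(tot / n^2)
}

# random rooted genealogy with <= n_nodes nodes, integer edge lengths
random_genealogy <- function(n_nodes = 6) {
  nodes <- paste0("n", seq_len(n_nodes))
  edges <- tibble::tibble(
    parent = vapply(2:n_nodes, function(i) nodes[sample(i - 1, 1)], character(1)),
    child = nodes[-1],
    length = sample(0:3, n_nodes - 1, replace = TRUE)
  )
  members <- sample(nodes, sample(2:6, 1), replace = TRUE)
  list(edges = edges, members = members, root = nodes[1])
}

# --- AMOVA oracle: explicit pair-loop computation of the one-level
# variance components ------------------------------------------------------
oracle_amova_fst <- function(hg, unit) {
  N <- length(hg)
  us <- unique(unit)
  G <- length(us)
  ssd_t <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    ssd_t <- ssd_t + as.numeric(hg[i] != hg[j])
  ssd_t <- ssd_t / (2 * N)
  ssd_w <- 0
  for (g in us) {
    idx <- which(unit == g)
    s <- 0
    for (i in idx) for (j in idx) s <- s + as.numeric(hg[i] != hg[j])
    ssd_w <- ssd_w + s / (2 * length(idx))
  }
  ssd_a <- ssd_t - ssd_w
  s2w <- ssd_w / (N - G)
  ng <- as.numeric(table(unit)[us])
  nprime <- (N - sum(ng^2) / N) / (G - 1)
  s2a <- (ssd_a / (G - 1) - s2w) / nprime
  if (s2a <= 0) 0 else s2a / (s2a + s2w)
}

# sample table with explicit haplogroup labels (STR columns unused)
hg_tbl <- function(hg, clan) {
  n <- length(hg)
  tibble::tibble(sample_id = paste0("s", seq_len(n)),
                 population = "pop", clan = clan, haplogroup = hg)
}
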