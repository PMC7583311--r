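# step distance, median-joining construction, clusters, jackknife

test_that("step distance is the summed absolute repeat difference", {
  expect_equal(step_distance(c(13, 29, 24), c(13, 29, 24)), 0)
  expect_equal(step_distance(c(10, 10), c(10, 12)), 2)
  expect_equal(step_distance(c(13, 29, 24), c(14, 28, 24)), 2)
  expect_equal(step_distance(c(a = 1, b = 5), c(b = 4, a = 1)), 1)  # name-aligned
  expect_error(step_distance(c(a = 1), c(b = 1)), "panel")
  expect_error(step_distance(c(1, NA), c(1, 2)), "missing")
})

test_that("two haplotypes one step apart give a single unit edge", {
  H <- rbind(c(10L, 10L, 10L), c(11L, 10L, 10L))
  net <- quiet_net(H)
  expect_equal(nrow(net$H), 2)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(igraph::E(net$graph)$weight, 1)
  expect_equal(sum(!net$nodes$sampled), 0)
})

test_that("a median equal to an existing haplotype adds no node", {
  # A=(10,10), B=(11,10), C=(10,11): their median is A itself
  H <- rbind(c(10L, 10L), c(11L, 10L), c(10L, 11L))
  net <- quiet_net(H)
  expect_equal(nrow(net$H), 3)
  expect_equal(sum(!net$nodes$sampled), 0)
  # star on A: B-C edge (weight 2) is excluded by the MSN rule
  expect_equal(igraph::ecount(net$graph), 2)
  expect_equal(net$cost, 2)
})

test_that("a cost-reducing Steiner median is inserted with degree >= 3", {
  # unit vectors: optimum needs the origin as a Steiner point (cost 4 -> 3)
  H <- rbind(c(11L, 10L, 10L), c(10L, 11L, 10L), c(10L, 10L, 11L))
  net <- quiet_net(H)
  expect_equal(net$cost, 3)
  expect_equal(sum(!net$nodes$sampled), 1)
  med <- net$nodes$node[!net$nodes$sampled]
  expect_equal(unname(net$H[med, ]), c(10L, 10L, 10L))
  expect_gte(igraph::degree(net$graph)[med], 3)
})

test_that("rectangle fixture matches the brute-force minimal cost", {
  H <- rbind(c(10L, 10L), c(12L, 10L), c(10L, 12L), c(12L, 12L))
  net <- quiet_net(H)
  expect_equal(net$cost, oracle_steiner_cost(H))
  # medians, if any survive pruning, must have degree >= 3
  mv <- net$nodes$node[!net$nodes$sampled]
  if (length(mv)) expect_true(all(igraph::degree(net$graph)[mv] >= 3))
})

test_that("network cost is monotone non-increasing and bounded by oracles", {
  set.seed(7)
  for (r in 1:40) {
    n <- sample(3:5, 1); L <- sample(2:3, 1)
    H <- unique(matrix(10L + sample(0:2, n * L, replace = TRUE), n, L))
    if (nrow(H) < 2) next
    net <- quiet_net(H)
    expect_true(all(diff(net$cost_trace) <= 1e-9))
    expect_lte(net$cost, oracle_mst_cost(unique(H)))
    expect_gte(net$cost + 1e-9, oracle_steiner_cost(unique(H)))
    mv <- net$nodes$node[!net$nodes$sampled]
    if (length(mv)) expect_true(all(igraph::degree(net$graph)[mv] >= 3))
  }
})

test_that("the network contains a sampled MST (geodesic-realised)", {
  # the network must realise some minimum spanning tree of the sampled
  # haplotypes as geodesic paths: since geodesics never undercut direct
  # step distances, this holds iff the MST cost of the geodesic metric
  # equals the MST cost of the direct step metric
  set.seed(8)
  for (r in 1:10) {
    H <- smm_star_fixture(n = sample(4:6, 1), L = 3)
    net <- quiet_net(H)
    ids <- net$nodes$node[net$nodes$sampled]
    Hs <- net$H[ids, , drop = FALSE]
    geo <- igraph::distances(net$graph, v = ids, to = ids,
                             weights = igraph::E(net$graph)$weight)
    g_geo <- igraph::graph_from_adjacency_matrix(geo, mode = "undirected",
                                                 weighted = TRUE)
    expect_equal(sum(igraph::E(igraph::mst(g_geo))$weight),
                 oracle_mst_cost(Hs))
  }
})

test_that("multiplicities are conserved and the network is connected", {
  pre <- three_founder_preset(n = 15)
  d <- suppressMessages(simulate_clans(pre$clans, pre$lineages, seed = 2))
  net <- suppressMessages(build_mj_network(d))
  expect_equal(net$n_samples, nrow(d))
  expect_equal(sum(net$nodes$multiplicity), nrow(d))
  expect_true(igraph::is_connected(net$graph))
  expect_true(all(igraph::E(net$graph)$weight >= 1))
})

test_that("construction is deterministic", {
  pre <- three_founder_preset(n = 12)
  d <- suppressMessages(simulate_clans(pre$clans, pre$lineages, seed = 4))
  n1 <- suppressMessages(build_mj_network(d))
  n2 <- suppressMessages(build_mj_network(d))
  expect_identical(n1$H, n2$H)
  expect_identical(igraph::as_edgelist(n1$graph), igraph::as_edgelist(n2$graph))
  expect_identical(n1$cost, n2$cost)
})

test_that("samples with missing network loci are excluded and logged", {
  H <- rbind(c(10L, 10L, 10L), c(11L, 10L, 10L), c(10L, 11L, 10L))
  d <- as_hap_tbl(H)
  d$L1[2] <- NA
  expect_message(ch <- condense_haplotypes(d, toy_panel(3)), "excluding 1")
  expect_equal(attr(ch, "excluded"), "s2")
  expect_equal(sum(ch$multiplicity), 2)
})

test_that("a single seed yields one cluster holding every sample", {
  H <- smm_star_fixture(6, 3)
  net <- quiet_net(H)
  cl <- extract_clusters(net, seeds = net$nodes$node[1])
  expect_equal(nrow(cl), sum(net$nodes$multiplicity))
  expect_equal(unique(cl$cluster), net$nodes$node[1])
})

test_that("path midpoint ties break toward the modal-nearest seed", {
  # 1D path 10-11-12-13-14; node 12 is equidistant from both seeds
  H <- cbind(10:14, rep(10L, 5))
  net <- quiet_net(H)
  cl <- extract_clusters(net, seeds = c("H001", "H005"))
  mid <- cl[cl$node == "H003", ]
  # all multiplicities tie, the global modal node is H001 (lexicographic),
  # and H001 is nearer to itself than H005 is
  expect_equal(mid$cluster, "H001")
  expect_error(extract_clusters(net, seeds = "H099"), "H099")
})

test_that("clusters recover the generating lineages of a 3-founder expansion", {
  pre <- three_founder_preset(n = 40, depth_generations = 25)
  d <- suppressMessages(simulate_clans(pre$clans, pre$lineages, seed = 21))
  net <- suppressMessages(build_mj_network(d))
  cl <- extract_clusters(net, k = 3)
  m <- merge(cl, sim_truth(d), by = "sample_id")
  purity <- sum(vapply(split(m$lineage, m$cluster),
                       function(x) max(table(x)), numeric(1))) / nrow(m)
  expect_gte(purity, 0.95)
})

test_that("jackknife degenerates to perfect agreement when almost nothing is dropped", {
  pre <- three_founder_preset(n = 12)
  d <- suppressMessages(simulate_clans(pre$clans, pre$lineages, seed = 6))
  js <- suppressMessages(jackknife_stability(d, fraction = 1e-6, reps = 1,
                                             seed = 1, k = 3))
  expect_equal(js$ari, 1)
  expect_equal(js$min_persistence, 1)
  expect_error(jackknife_stability(d, fraction = 1.2, reps = 1), "fraction")
})

test_that("a one-cluster dataset persists through every replicate", {
  spec <- three_founder_preset(n = 30)$lineages$L1
  d <- suppressMessages(simulate_lineage(spec, n = 30, seed = 9))
  d$population <- "p"
  js <- suppressMessages(jackknife_stability(d, fraction = 0.1, reps = 5,
                                             seed = 2, k = 1))
  expect_true(all(js$min_persistence == 1))
})

test_that("GraphML export round-trips node multiplicities", {
  H <- smm_star_fixture(5, 3)
  net <- quiet_net(H)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(net$H))
  expect_equal(sort(igraph::V(g2)$multiplicity),
               sort(unname(net$nodes$multiplicity)))
})
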