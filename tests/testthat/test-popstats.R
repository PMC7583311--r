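# haplotype diversity, AMOVA F_ST, Nei distance, ordination

test_that("haplotype diversity spans its closed-form anchor cases", {
  expect_equal(haplotype_diversity(rep("h1", 10)), 0)
  expect_equal(haplotype_diversity(c("h1", "h2")), 1)
  expect_error(haplotype_diversity("h1"), "at least 2")
  set.seed(3)
  for (r in 1:20) {
    keys <- sample(letters[1:5], sample(2:30, 1), replace = TRUE)
    hd <- haplotype_diversity(keys)
    expect_gte(hd, 0); expect_lte(hd, 1)
    relab <- stats::setNames(sample(LETTERS[1:5]), letters[1:5])
    expect_equal(haplotype_diversity(unname(relab[keys])), hd)
  }
})

test_that("haplotype diversity works directly on sample tables", {
  H <- rbind(c(10L, 10L), c(10L, 10L), c(11L, 10L), c(12L, 13L))
  d <- as_hap_tbl(H)
  # frequencies 2/4, 1/4, 1/4 -> HD = 4/3 * (1 - 6/16)
  expect_equal(haplotype_diversity(d, toy_panel(2)), 4 / 3 * (1 - 6 / 16))
})

test_that("AMOVA hits the fixed-difference and identical-composition anchors", {
  fixed <- hg_tbl(c(rep("A", 6), rep("B", 6)),
                  clan = rep(c("u1", "u2"), each = 6))
  expect_equal(amova_fst(fixed, units = "clan")$fst, 1)

  same <- hg_tbl(rep(c("A", "A", "B"), 4),
                 clan = rep(c("u1", "u2"), each = 6))
  expect_equal(amova_fst(same, units = "clan")$fst, 0)
})

test_that("AMOVA equals the explicit pair-loop oracle on random datasets", {
  set.seed(23)
  for (r in 1:20) {
    n <- sample(9:20, 1)
    hg <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
    unit <- sample(c("u1", "u2", "u3"), n, replace = TRUE)
    if (length(unique(unit)) < 3) next
    d <- hg_tbl(hg, clan = unit)
    got <- amova_fst(d, units = "clan")
    expect_equal(got$fst, oracle_amova_fst(hg, unit), tolerance = 1e-12)
    # permutation invariance
    p <- sample(n)
    expect_equal(amova_fst(d[p, ], units = "clan")$fst, got$fst,
                 tolerance = 1e-12)
  }
})

test_that("merged-unit schemes map clans before decomposing variance", {
  d <- hg_tbl(c(rep("A", 4), rep("A", 4), rep("B", 4)),
              clan = rep(c("c1", "c2", "c3"), each = 4))
  merged <- amova_fst(d, units = c(c1 = "core", c2 = "core", c3 = "c3"))
  expect_equal(merged$n_units, 2)
  expect_equal(merged$fst, oracle_amova_fst(d$haplogroup,
                                            c(rep("core", 8), rep("c3", 4))))
  g <- glance(merged)
  expect_named(g, c("fst", "n", "n_units", "scheme", "distance"))
})

test_that("Nei distance matches hand-evaluated anchors and is symmetric", {
  f <- rbind(x = c(0.5, 0.5), y = c(1, 0), z = c(0.5, 0.5))
  D <- nei_distance(f)
  expect_equal(D["x", "z"], 0)
  expect_equal(D["x", "y"], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)  # 0.3466
  expect_equal(unname(D["x", "y"]), 0.3466, tolerance = 1e-4)
  expect_true(isSymmetric(unclass(unname(D))))
  expect_true(all(diag(D) == 0))
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(nei_distance(disj)["a", "b"], Inf)
})

test_that("classical MDS reproduces exact geometry on small matrices", {
  # three equidistant groups -> equilateral triangle
  D <- matrix(2, 3, 3); diag(D) <- 0
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  md <- ordinate(D, "mds")
  pts <- as.matrix(md[, c("axis1", "axis2")])
  out <- as.matrix(stats::dist(pts))
  expect_true(all(abs(out[upper.tri(out)] - 2) < 1e-9))

  # Euclidean-embeddable 4-point configuration is reproduced exactly
  set.seed(5)
  X <- matrix(rnorm(8), 4, 2)
  D4 <- as.matrix(stats::dist(X))
  rownames(D4) <- colnames(D4) <- paste0("g", 1:4)
  md4 <- ordinate(D4, "mds")
  out4 <- as.matrix(stats::dist(as.matrix(md4[, c("axis1", "axis2")])))
  expect_true(all(abs(out4 - unname(D4)) < 1e-9))
  expect_error(ordinate(matrix(c(0, 1, 2, 0), 2, 2), "mds"), "symmetric")
})

test_that("rank-1 frequency matrices load entirely on the first component", {
  # two-category profiles lie on a line, so the centered matrix has rank 1
  f <- rbind(g1 = c(0.3, 0.7), g2 = c(0.6, 0.4), g3 = c(0.9, 0.1))
  p <- ordinate(f, "pca")
  expect_equal(attr(p, "diagnostics")[1], 1, tolerance = 1e-12)
})

test_that("Ward clustering exports a readable Newick dendrogram", {
  f <- rbind(a = c(0.9, 0.1, 0), b = c(0.8, 0.2, 0),
             c = c(0.1, 0.1, 0.8), d = c(0, 0.2, 0.8))
  D <- nei_distance(f)
  hc <- ordinate(D, "ward")
  expect_s3_class(hc, "hclust")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("a", "b", "c", "d"))
})

test_that("core groups stay mutual nearest neighbours in MDS space", {
  # four near-identical "core" profiles and three distinct outliers
  set.seed(41)
  core <- matrix(rep(c(0.6, 0.2, 0.1, 0.1, 0, 0), 4), 4, byrow = TRUE) +
    matrix(runif(24, 0, 0.02), 4)
  out <- rbind(c(0, 0, 0.1, 0, 0.8, 0.1),
               c(0.05, 0, 0, 0.05, 0.1, 0.8),
               c(0.1, 0.8, 0.05, 0.05, 0, 0))
  f <- rbind(core, out)
  f <- f / rowSums(f)
  rownames(f) <- c(paste0("core", 1:4), paste0("far", 1:3))
  md <- ordinate(nei_distance(f), "mds")
  pts <- as.matrix(md[, c("axis1", "axis2")])
  rownames(pts) <- md$group
  D <- as.matrix(stats::dist(pts))
  for (g in paste0("core", 1:4)) {
    nn <- names(which.min(D[g, setdiff(rownames(D), g)]))
    expect_match(nn, "^core")
  }
})
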