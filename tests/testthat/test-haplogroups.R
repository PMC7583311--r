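# haplogroup tree walk, downstream subclades, STR motif, frequency tables

tr <- snp_backbone_tree()
sub <- c2st_tree()

test_that("shipped trees validate and cover the expected marker panels", {
  expect_length(tr$marker, 35)
  expect_s3_class(tr, "haplogroup_tree")
  expect_true(all(c("M130", "M217", "M48", "M407", "M178", "P58") %in% tr$marker))
  expect_true(all(c("F3796", "F8951", "F5481", "Y12782") %in% sub$marker))
  # every parent chain terminates at ROOT (depth computed without error)
  expect_true(all(tr$depth >= 1))
})

test_that("tree files with duplicated markers or cycles are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(haplogroup = c("A", "B"),
                                  marker = c("m1", "m1"),
                                  parent = c("ROOT", "ROOT")), path)
  expect_error(read_haplogroup_tree(path), "duplicated")
  readr::write_tsv(tibble::tibble(haplogroup = c("A", "B"),
                                  marker = c("m1", "m2"),
                                  parent = c("m2", "m1")), path)
  expect_error(read_haplogroup_tree(path), "cycle|root")
})

test_that("assignment returns the deepest confirmed clade with (x...) labels", {
  expect_equal(
    assign_haplogroup(c(M130 = "derived", M217 = "derived",
                        M48 = "ancestral", M407 = "ancestral"), tr),
    "C2-M217(xM48, M407)")
  expect_equal(assign_haplogroup(c(M231 = "derived", M178 = "derived"), tr),
               "N1a1a-M178")
  expect_equal(assign_haplogroup(c(M267 = "derived", P58 = "ancestral"), tr),
               "J1-M267(xP58)")
  all_anc <- stats::setNames(rep("ancestral", 35), tr$marker)
  expect_equal(assign_haplogroup(all_anc, tr), "Y*")
  # missing calls are untested, not negative: no (x...) entry, no descent
  expect_equal(assign_haplogroup(c(M130 = "derived", M217 = "derived"), tr),
               "C2-M217")
})

test_that("a derived call under an ancestral parent raises a named error", {
  expect_error(
    assign_haplogroup(c(M130 = "ancestral", M217 = "derived"), tr),
    "M217.*M130")
})

test_that("assignment is monotone in added derived calls", {
  depth_of <- stats::setNames(tr$depth, tr$marker)
  label_depth <- function(calls) {
    lab <- assign_haplogroup(calls, tr, annotate = "none")
    if (lab == "Y*") 0L else unname(depth_of[tr$marker[tr$haplogroup == lab]])
  }
  set.seed(42)
  for (rep in 1:25) {
    m <- sample(tr$marker, 1)
    # full derived path to m, revealed one call at a time from the top
    chain <- character()
    cur <- m
    while (cur != "ROOT") {
      chain <- c(cur, chain)
      cur <- tr$parent[match(cur, tr$marker)]
    }
    prev <- 0L
    for (k in seq_along(chain)) {
      calls <- stats::setNames(rep("derived", k), chain[seq_len(k)])
      d <- label_depth(calls)
      expect_gte(d, prev)
      prev <- d
    }
  }
})

test_that("downstream C2*-ST subclades follow the F3796 topology", {
  expect_equal(
    assign_haplogroup(c(M217 = "derived", F3796 = "derived",
                        F5481 = "derived", Y12782 = "derived"),
                      sub, annotate = "star"),
    "Y12782")
  expect_equal(
    assign_haplogroup(c(M217 = "derived", F8951 = "derived"), sub,
                      annotate = "star"),
    "F8951")
  calls <- c(M217 = "derived", F3796 = "derived", F5481 = "derived",
             SK1076 = "ancestral", F8949 = "ancestral", F9033 = "ancestral",
             F11165 = "ancestral", Y12782 = "ancestral")
  expect_equal(assign_haplogroup(calls, sub, annotate = "star"), "F5481*")
})

test_that("assign_c2_downstream leaves untyped samples unassigned", {
  d <- tibble::tibble(sample_id = c("a", "b"), population = "p", clan = "c",
                      M217 = c("derived", "derived"),
                      F3796 = c("derived", NA),
                      F5481 = c("derived", NA),
                      Y12782 = c("derived", NA))
  out <- suppressMessages(assign_c2_downstream(d))
  expect_equal(out$c2_subclade, c("Y12782", NA))
})

test_that("STR-motif classification applies the step threshold exactly", {
  motif <- c2st_motif()
  h <- motif$centroid
  expect_true(classify_c2st_by_str(h, motif))
  h2 <- h; h2[1] <- h2[1] + motif$max_steps + 1L
  expect_false(classify_c2st_by_str(h2, motif))
  m3 <- c2st_motif(max_steps = 3)
  h3 <- m3$centroid; h3["DYS19"] <- h3["DYS19"] + 1L  # hand step distance 1
  expect_true(classify_c2st_by_str(h3, m3))
  h4 <- h; h4[1] <- NA
  expect_error(classify_c2st_by_str(h4, motif), "missing")
})

test_that("frequency rows sum to one and counts to group sizes", {
  d <- hg_tbl(c(rep("N1a1a-M178", 8), rep("C2-M217", 2),
                rep("A", 1), rep("B", 3)),
              clan = c(rep("Syrgeli", 10), rep("Toy", 4)))
  f <- hg_frequencies(d, "clan")
  expect_equal(f$freq[f$group == "Syrgeli" & f$haplogroup == "N1a1a-M178"], 0.8)
  expect_equal(sort(f$freq[f$group == "Toy"]), c(0.25, 0.75))
  sums <- tapply(f$freq, f$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(unname(attr(f, "group_sizes")[c("Syrgeli", "Toy")]), c(10L, 4L))
  g <- glance(f)
  expect_equal(g$n_samples, 14L)
})

test_that("ten samples of one haplogroup give frequency 1", {
  f <- hg_frequencies(hg_tbl(rep("Q-M242", 10), clan = "Kanly"), "clan")
  expect_equal(f$freq, 1)
  expect_equal(f$n, 10L)
})

test_that("assignment recovers the generating haplogroup for complete profiles", {
  pre <- senior_zhuz_preset()
  d <- suppressMessages(simulate_clans(pre$clans, pre$lineages, seed = 5))
  d <- suppressMessages(assign_haplogroups(d))
  truth <- sim_truth(d)
  expected <- c(C2ST_gamma = "C2-M217(xM48, M407)",
                C2ST_alpha = "C2-M217(xM48, M407)",
                C2ST_beta = "C2-M217(xM48, M407)",
                C2_M48 = "C2-M48", C2_M407 = "C2-M407",
                N1a1a = "N1a1a-M178", J1 = "J1-M267(xP58)",
                J2 = "J2-M172(xM47, M67, M12)", Q = "Q-M242", G2 = "G2-P15",
                R1a = "R1a1a-M198", O2 = "O2-M122(xM134)", R1b = "R1b1a-M269",
                I1 = "I1-M253")
  got <- merge(d[, c("sample_id", "haplogroup")], truth, by = "sample_id")
  expect_identical(got$haplogroup, unname(expected[got$lineage]))
})
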