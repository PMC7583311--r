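#' Lineage and clan specifications for the forward simulator
#'
#' A lineage is one founder paternal line: a founder STR haplotype, the
#' haplogroup it belongs to (as the defining marker of the deepest node;
#' all markers on the root path are set derived in simulated SNP
#' profiles, optional `extra_derived` markers cover downstream subclade
#' panels), a depth in generations, and a growth mode. A clan is a named
#' mixture of lineages; each sampled man draws his lineage from the
#' mixture, then descends from its founder under the stepwise mutation
#' model.
#'
#' @param name Lineage name (ground-truth label).
#' @param founder_haplotype Named integer vector of repeat counts over the
#'   full locus panel.
#' @param founder_marker Defining SNP marker of the lineage's haplogroup
#'   in the backbone tree.
#' @param extra_derived Further derived markers (e.g. C2*-ST downstream).
#' @param depth_generations Generations from founder to the present.
#' @param growth `"star"` (every sample is an independent line from the
#'   founder) or `"exponential"` (forward branching to roughly the target
#'   number of tips).
#' @param n Default number of samples when simulated standalone.
#' @return A list of class `lineage_spec` / `clan_spec`.
#' @export
lineage_spec <- function(name, founder_haplotype, founder_marker,
                         extra_derived = character(),
                         depth_generations = 25,
                         growth = c("star", "exponential"), n = NULL) {
  growth <- match.arg(growth)
  stopifnot(depth_generations >= 0, !is.null(names(founder_haplotype)))
  structure(list(name = name, founder_haplotype = founder_haplotype,
                 founder_marker = founder_marker,
                 extra_derived = extra_derived,
                 depth_generations = as.integer(depth_generations),
                 growth = growth, n = n),
            class = "lineage_spec")
}

#' @rdname lineage_spec
#' @param mixture Named list `lineage_name -> proportion`; proportions sum
#'   to 1. Lineage objects are resolved from `lineages` in
#'   [simulate_clans()].
#' @export
clan_spec <- function(name, n, mixture) {
  stopifnot(abs(sum(unlist(mixture)) - 1) < 1e-9, n >= 1)
  structure(list(name = name, n = as.integer(n), mixture = mixture),
            class = "clan_spec")
}

# SNP profile (calls for every marker of the backbone tree, plus the
# downstream set when extra_derived touches it) implied by a lineage
.lineage_snp_calls <- function(spec, tree = snp_backbone_tree(),
                               sub_tree = c2st_tree()) {
  path <- .tree_path(tree, spec$founder_marker)
  calls <- setNames(rep("ancestral", nrow(tree)), tree$marker)
  calls[path] <- "derived"
  if (length(spec$extra_derived)) {
    sub <- setNames(rep("ancestral", nrow(sub_tree)), sub_tree$marker)
    for (m in spec$extra_derived) sub[.tree_path(sub_tree, m)] <- "derived"
    sub <- sub[setdiff(names(sub), names(calls))]
    calls <- c(calls, sub)
  }
  calls
}

# SMM displacement for n lineages over `gens` generations on L loci:
# events per lineage-locus ~ Binomial(gens, mu), each event a +/-1 step.
.smm_displace <- function(n, L, gens, mu) {
  ev <- matrix(rbinom(n * L, gens, mu), n, L)
  disp <- matrix(2L * rbinom(n * L, as.vector(ev), 0.5) - as.vector(ev), n, L)
  list(disp = disp, events = ev)
}

#' Simulate one paternal lineage under the stepwise mutation model
#'
#' Each sampled chromosome descends `depth_generations` from the founder;
#' per generation and locus it mutates with probability `mu`, stepping
#' +/-1 repeat with equal probability. Star growth gives every sample an
#' independent line of descent; exponential growth runs a forward
#' branching process (per-generation split probability calibrated so the
#' expected tip count reaches `n`) and samples `n` tips from it, so lines
#' share internal branches.
#'
#' @param spec A [lineage_spec()].
#' @param n Number of samples (default `spec$n`).
#' @param mu Mutation rate per locus per generation.
#' @param seed Optional RNG seed.
#' @param id_prefix Prefix for generated sample IDs.
#' @param tree,sub_tree Haplogroup trees used to spell out SNP calls.
#' @return Sample table (tibble) with STR and SNP columns; ground truth
#'   (per-sample lineage, mutation-event count, depth) in attribute
#'   `"truth"`, panel in attribute `"panel"`.
#' @export
simulate_lineage <- function(spec, n = spec$n, mu = 2.1e-3, seed = NULL,
                             id_prefix = spec$name,
                             tree = snp_backbone_tree(),
                             sub_tree = c2st_tree()) {
  stopifnot(inherits(spec, "lineage_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  founder <- spec$founder_haplotype
  loci <- names(founder)
  L <- length(loci)
  T_ <- spec$depth_generations

  if (spec$growth == "star" || T_ == 0) {
    sm <- .smm_displace(n, L, T_, mu)
    H <- sweep(sm$disp, 2, as.integer(founder), `+`)
    n_mut <- rowSums(sm$events)
  } else {
    # forward branching: split probability p gives E[tips] = (1+p)^T = n
    p <- max(0, n^(1 / T_) - 1)
    H <- matrix(as.integer(founder), 1, L, byrow = TRUE)
    n_mut <- 0L
    cap <- max(4L * n, 16L)
    for (g in seq_len(T_)) {
      if (nrow(H) < cap) {
        split <- runif(nrow(H)) < p
        if (any(split)) {
          H <- rbind(H, H[split, , drop = FALSE])
          n_mut <- c(n_mut, n_mut[split])
        }
      }
      sm <- .smm_displace(nrow(H), L, 1L, mu)
      H <- H + sm$disp
      n_mut <- n_mut + rowSums(sm$events)
    }
    pick <- sample.int(nrow(H), n, replace = nrow(H) < n)
    H <- H[pick, , drop = FALSE]
    n_mut <- n_mut[pick]
  }
  colnames(H) <- loci

  snp <- .lineage_snp_calls(spec, tree, sub_tree)
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids, population = NA_character_,
                   clan = NA_character_),
    tibble::as_tibble(H),
    tibble::as_tibble(as.list(snp))[rep(1, n), ]
  )
  attr(out, "panel") <- ystr_panel(loci,
    multi_copy = intersect(c("DYS385a", "DYS385b"), loci))
  attr(out, "truth") <- tibble::tibble(
    sample_id = ids, lineage = spec$name, n_mutations = n_mut,
    depth_generations = T_)
  out
}

#' Simulate a multi-clan dataset with ground truth
#'
#' Draws each clan's samples from its lineage mixture (multinomial), then
#' simulates every lineage's descendants with [simulate_lineage()]. The
#' result is one merged sample table in exactly the format
#' [read_samples()] produces, ready for the full pipeline, with the
#' generating truth attached.
#'
#' @param clans List of [clan_spec()]s (unique names).
#' @param lineages Named list of [lineage_spec()]s referenced by the clan
#'   mixtures.
#' @param mu Mutation rate per locus per generation.
#' @param seed RNG seed.
#' @param population Population label stamped on all samples.
#' @return Sample table (tibble) with attributes `"panel"` and `"truth"`
#'   (tibble: sample_id, clan, lineage, n_mutations, depth_generations).
#' @export
simulate_clans <- function(clans, lineages, mu = 2.1e-3, seed = NULL,
                           population = "simulated") {
  nm <- vapply(clans, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("clan name collision: ",
                              paste(nm[duplicated(nm)], collapse = ", "),
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  samples <- list(); truths <- list()
  for (cl in clans) {
    lin_names <- names(cl$mixture)
    missing <- setdiff(lin_names, names(lineages))
    if (length(missing)) stop("clan ", cl$name, " references unknown lineage(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    counts <- as.vector(stats::rmultinom(1, cl$n, unlist(cl$mixture)))
    for (k in seq_along(lin_names)) {
      if (counts[k] == 0) next
      sim <- simulate_lineage(lineages[[lin_names[k]]], n = counts[k], mu = mu,
                              id_prefix = paste0(cl$name, "_", lin_names[k]))
      sim$population <- population
      sim$clan <- cl$name
      tr <- attr(sim, "truth")
      tr$clan <- cl$name
      samples[[length(samples) + 1L]] <- sim
      truths[[length(truths) + 1L]] <- tr
    }
  }
  panel <- attr(samples[[1]], "panel")
  out <- dplyr::bind_rows(samples)
  attr(out, "panel") <- panel
  attr(out, "truth") <- dplyr::bind_rows(truths)
  message(sprintf("simulated %d samples across %d clans (%d lineages)",
                  nrow(out), length(clans),
                  dplyr::n_distinct(attr(out, "truth")$lineage)))
  out
}

#' @rdname simulate_clans
#' @param data A simulated sample table.
#' @export
sim_truth <- function(data) {
  tr <- attr(data, "truth")
  if (is.null(tr)) stop("no ground truth attached to this table", call. = FALSE)
  tr
}

# shift selected loci of a founder haplotype (helper for presets)
.shift_hap <- function(base, at, by) { base[at] <- base[at] + by; base }

# full 17-locus founder used by the C2*-ST-like lineages: the shipped
# motif centroid plus assumed DYS385a/b alleles
.c2st_founder17 <- function() {
  m <- c2st_motif()$centroid
  c(m, DYS385a = 12L, DYS385b = 18L)[yfiler17_panel()$loci]
}

#' Shipped simulation presets
#'
#' `three_founder_preset()` is the workhorse for network/cluster
#' validation: one population, three star-expanding lineages of equal
#' depth whose founder haplotypes are 8+ mutational steps apart.
#'
#' `senior_zhuz_preset()` emulates the study design this package is built
#' around: a core of clans dominated (40-60%) by one young C2*-ST lineage
#' (the "gamma"-like founder, depth 25 generations ~ 750 years), a second
#' C2*-ST lineage concentrated in one non-core clan ("alpha"-like, F5481*
#' subclade) and a minor third one ("beta"-like, F8949), plus clans fixed
#' for other haplogroups (80% N1a1a, 75% J1, 55% Q, 35% G2) and older
#' background lineages (J2, R1a, O2, ...) at realistic frequencies.
#'
#' @param n Per-lineage sample count (three-founder preset).
#' @param depth_generations Expansion depth of the three founders.
#' @return A list with elements `clans` and `lineages`, ready for
#'   [simulate_clans()].
#' @export
three_founder_preset <- function(n = 40, depth_generations = 25) {
  f <- .c2st_founder17()
  lineages <- list(
    L1 = lineage_spec("L1", f, "M217", c("F3796", "F5481", "Y12782"),
                      depth_generations),
    L2 = lineage_spec("L2", .shift_hap(f, c("DYS19", "DYS390", "DYS391", "DYS439"), 2L),
                      "M217", c("F3796", "F5481"), depth_generations),
    L3 = lineage_spec("L3", .shift_hap(f, c("DYS392", "DYS437", "DYS448", "DYS458"), -2L),
                      "M217", c("F3796", "F5481", "F8949"), depth_generations)
  )
  clans <- list(clan_spec("A", n, list(L1 = 1)),
                clan_spec("B", n, list(L2 = 1)),
                clan_spec("C", n, list(L3 = 1)))
  list(clans = clans, lineages = lineages)
}

#' @rdname three_founder_preset
#' @export
senior_zhuz_preset <- function() {
  f <- .c2st_founder17()
  up <- function(at, by) .shift_hap(f, at, as.integer(by))
  lineages <- list(
    C2ST_gamma = lineage_spec("C2ST_gamma", f, "M217",
                              c("F3796", "F5481", "Y12782"), 25),
    C2ST_alpha = lineage_spec("C2ST_alpha",
                              up(c("DYS19", "DYS390", "DYS391", "DYS439"), 1),
                              "M217", c("F3796", "F5481"), 25),
    C2ST_beta = lineage_spec("C2ST_beta",
                             up(c("DYS392", "DYS437", "DYS448", "DYS458"), -1),
                             "M217", c("F3796", "F5481", "F8949"), 25),
    C2_M48 = lineage_spec("C2_M48", up(c("DYS19", "DYS389I", "DYS456", "DYS635"), 3),
                          "M48", depth_generations = 60),
    C2_M407 = lineage_spec("C2_M407", up(c("DYS390", "DYS392", "DYS458", "GATA_H4"), -3),
                           "M407", depth_generations = 60),
    N1a1a = lineage_spec("N1a1a", up(c("DYS19", "DYS390", "DYS391", "DYS392", "DYS437"), -2),
                         "M178", depth_generations = 40),
    J1 = lineage_spec("J1", up(c("DYS389I", "DYS439", "DYS448", "DYS456", "DYS458"), 2),
                      "M267", depth_generations = 50),
    J2 = lineage_spec("J2", up(c("DYS393", "DYS437", "DYS438", "DYS439", "DYS635"), 3),
                      "M172", depth_generations = 60),
    Q = lineage_spec("Q", up(c("DYS19", "DYS391", "DYS438", "DYS448", "GATA_H4"), -3),
                     "M242", depth_generations = 50),
    G2 = lineage_spec("G2", up(c("DYS389I", "DYS390", "DYS456", "DYS458", "DYS635"), -2),
                      "P15", depth_generations = 50),
    R1a = lineage_spec("R1a", up(c("DYS19", "DYS392", "DYS393", "DYS439", "DYS448"), 3),
                       "M198", depth_generations = 50),
    O2 = lineage_spec("O2", up(c("DYS390", "DYS391", "DYS437", "DYS456", "GATA_H4"), 2),
                      "M122", depth_generations = 60),
    R1b = lineage_spec("R1b", up(c("DYS19", "DYS389I", "DYS392", "DYS635"), -4),
                       "M269", depth_generations = 60),
    I1 = lineage_spec("I1", up(c("DYS391", "DYS393", "DYS438", "DYS458"), 4),
                      "M253", depth_generations = 60)
  )
  clans <- list(
    clan_spec("Dulat", 60, list(C2ST_gamma = .50, C2ST_beta = .05, J2 = .15,
                                R1a = .15, O2 = .10, R1b = .05)),
    clan_spec("Alban", 55, list(C2ST_gamma = .45, Q = .15, J2 = .15,
                                R1a = .10, N1a1a = .10, I1 = .05)),
    clan_spec("Suan", 30, list(C2ST_gamma = .50, J2 = .20, R1a = .15, O2 = .15)),
    clan_spec("Sary-Uissun", 25, list(C2ST_gamma = .60, C2_M407 = .15, J2 = .25)),
    clan_spec("Shaprashty", 40, list(C2ST_gamma = .40, C2_M48 = .10, J2 = .20,
                                     Q = .15, R1a = .15)),
    clan_spec("Oshakty", 35, list(C2ST_gamma = .20, J2 = .35, R1a = .25, Q = .20)),
    clan_spec("Jalair", 45, list(C2ST_alpha = .55, C2ST_gamma = .10, J2 = .15,
                                 R1a = .20)),
    clan_spec("Syrgeli", 40, list(N1a1a = .80, C2ST_gamma = .10, J2 = .10)),
    clan_spec("Yssty", 35, list(J1 = .75, C2ST_gamma = .10, Q = .15)),
    clan_spec("Kanly", 35, list(Q = .55, C2ST_gamma = .15, J2 = .15, R1a = .15)),
    clan_spec("Shanyshkly", 20, list(G2 = .35, C2ST_gamma = .20, C2_M48 = .10,
                                     J2 = .15, R1a = .20))
  )
  list(clans = clans, lineages = lineages)
}
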