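#' Run configuration
#'
#' The whole analysis is driven by one configuration (an R list or a YAML
#' file): input (a sample table path, or a named simulation preset),
#' panel/tree settings, network parameters, dating calibration, AMOVA
#' grouping schemes, jackknife settings, an output directory and one RNG
#' seed. Defaults follow the package's standard calibration (mu = 2.1e-3
#' per locus per generation, 30-year generations, 15 network loci,
#' epsilon = 0, 10% jackknife omission).
#'
#' @param path YAML file, or `NULL` to get the default config.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(
    input = list(preset = "senior_zhuz", path = NULL,
                 dys389_format = "separate"),
    network = list(epsilon = 0, k = 3, seeds = NULL),
    dating = list(mu = 2.1e-3, n_loci = 15, gen_years = 30, z = 1.96),
    amova = NULL,             # named list: scheme name -> clan->unit map
    jackknife = list(enabled = FALSE, fraction = 0.10, reps = 100),
    seed = 1,
    out_dir = NULL
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(user[[k]]) && is.list(cfg[[k]]))
        utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
    }
    if (!is.null(cfg$input$path) && !file.exists(cfg$input$path))
      stop("input file does not exist: ", cfg$input$path, call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

# select the C2*-ST subset: downstream SNP calls when present, otherwise
# the STR motif
.select_c2st <- function(data, motif = c2st_motif()) {
  if ("F3796" %in% names(data) && any(!is.na(data$F3796))) {
    sel <- !is.na(data$F3796) & data$F3796 == "derived"
    method <- "SNP (F3796 derived)"
  } else {
    data <- classify_c2st(data, motif)
    sel <- !is.na(data$c2st_str) & data$c2st_str
    method <- sprintf("STR motif (<= %d steps)", motif$max_steps)
  }
  message(sprintf("C2*-ST selection by %s: %d of %d samples",
                  method, sum(sel), nrow(data)))
  data[sel, , drop = FALSE]
}

#' Run the full clan-structure pipeline
#'
#' Executes every stage in order — read or simulate, haplogroup
#' assignment (backbone, plus downstream C2*-ST subclades when those
#' markers are present), frequency profiling, C2*-ST subset selection,
#' median-joining network, cluster extraction, rho/TMRCA dating,
#' diversity, AMOVA, Nei distances and ordination, optional jackknife —
#' writing every intermediate artifact to `cfg$out_dir` (frequency CSV,
#' GraphML network, cluster CSV, dating table, stats tables, JSON
#' summary). Deterministic for a given config and seed.
#'
#' @param cfg A [read_run_config()] list (or a YAML path).
#' @return The report bundle (named list), invisibly.
#' @export
run_pipeline <- function(cfg = read_run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  set.seed(cfg$seed)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }

  # --- input ---------------------------------------------------------------
  data <- if (!is.null(cfg$input$path)) {
    read_samples(cfg$input$path, dys389_format = cfg$input$dys389_format)
  } else {
    preset <- switch(cfg$input$preset,
                     senior_zhuz = senior_zhuz_preset(),
                     three_founder = three_founder_preset(),
                     stop("unknown preset: ", cfg$input$preset, call. = FALSE))
    simulate_clans(preset$clans, preset$lineages, mu = cfg$dating$mu,
                   seed = cfg$seed)
  }
  emit("samples.tsv", function(p) write_samples(data, p))

  # --- haplogroups ---------------------------------------------------------
  data <- assign_haplogroups(data)
  if (any(c2st_downstream_markers() %in% names(data)))
    data <- assign_c2_downstream(data)
  freq <- hg_frequencies(data, group = "clan")
  emit("haplogroup_frequencies.csv", function(p) readr::write_csv(freq, p))

  # --- C2*-ST network, clusters, dating -----------------------------------
  c2 <- .select_c2st(data)
  net <- build_mj_network(c2, epsilon = cfg$network$epsilon, label = "clan")
  emit("network.graphml", function(p) write_network(net, p))
  clusters <- extract_clusters(net, seeds = cfg$network$seeds,
                               k = cfg$network$k)
  emit("clusters.csv", function(p) readr::write_csv(clusters, p))
  params <- dating_params(cfg$dating$mu, cfg$dating$n_loci,
                          cfg$dating$gen_years, cfg$dating$z)
  dating <- date_clusters(net, clusters, params = params)
  overall <- {
    all_members <- clusters
    founder <- net$nodes$node[order(-net$nodes$multiplicity, net$nodes$node)][1]
    rho <- rho_statistic(net, all_members, founder)
    gen <- cluster_genealogy(net, all_members, founder)
    sig <- if (nrow(gen)) sigma_rho(gen, all_members$node) else 0
    dplyr::bind_cols(tibble::tibble(cluster = "(all C2*-ST)", founder = founder),
                     tmrca(rho, sig, n = nrow(all_members), params = params))
  }
  dating <- dplyr::bind_rows(dating, overall)
  emit("tmrca.csv", function(p) readr::write_csv(dating, p))

  # --- population statistics ----------------------------------------------
  hd <- haplotype_diversity(c2)
  amova <- list()
  if (dplyr::n_distinct(stats::na.omit(data$clan)) >= 2) {
    amova$clans <- glance(amova_fst(data, units = "clan"))
  } else {
    message("AMOVA by clan skipped: fewer than 2 clans")
  }
  for (nm in names(cfg$amova %||% list())) {
    amova[[nm]] <- glance(amova_fst(data, units = unlist(cfg$amova[[nm]])))
  }
  amova_tbl <- dplyr::bind_rows(amova, .id = "scheme_name")
  if (dplyr::n_distinct(freq$group) >= 3) {
    nei <- nei_distance(freq)
    mds <- ordinate(nei, "mds")
    pca <- ordinate(freq, "pca")
    ward <- ordinate(nei, "ward")
    emit("nei_distances.csv", function(p)
      readr::write_csv(tibble::as_tibble(as.data.frame(unclass(nei)),
                                         rownames = "group"), p))
    emit("mds.csv", function(p) readr::write_csv(mds, p))
    emit("pca.csv", function(p) readr::write_csv(pca, p))
    emit("ward.nwk", function(p) write_dendrogram_newick(ward, p))
  } else {
    message("ordination skipped: fewer than 3 groups")
  }

  jack <- NULL
  if (isTRUE(cfg$jackknife$enabled)) {
    jack <- jackknife_stability(c2, fraction = cfg$jackknife$fraction,
                                reps = cfg$jackknife$reps, seed = cfg$seed,
                                k = cfg$network$k, label = "clan")
    emit("jackknife.csv", function(p) readr::write_csv(jack, p))
  }

  # --- report --------------------------------------------------------------
  report <- list(
    seed = cfg$seed,
    n_samples = nrow(data),
    n_haplogroups = attr(freq, "n_haplogroups"),
    frequencies = as.data.frame(freq),
    c2st = list(n = nrow(c2), haplotype_diversity = hd),
    network = as.data.frame(glance(net)),
    clusters = as.data.frame(attr(clusters, "summary")),
    tmrca = as.data.frame(dating),
    amova = as.data.frame(amova_tbl),
    parameters = unclass(params)
  )
  if (!is.null(jack))
    report$jackknife <- as.data.frame(glance(jack))
  if (!is.null(out_dir))
    write_report(report, file.path(out_dir, "summary.json"))
  invisible(report)
}
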