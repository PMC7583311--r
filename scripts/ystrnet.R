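#!/usr/bin/env Rscript
# Thin command-line wrapper over the installed ystrnet package.
#
#   Rscript scripts/ystrnet.R run      --config cfg.yaml --out DIR [--seed N]
#   Rscript scripts/ystrnet.R simulate --preset senior_zhuz|three_founder --seed N --out DIR
#   Rscript scripts/ystrnet.R assign   --input samples.tsv --out assigned.tsv
#   Rscript scripts/ystrnet.R network  --input assigned.tsv --out DIR [--epsilon N] [--k N]
#   Rscript scripts/ystrnet.R date     --input assigned.tsv --out DIR [--k N]
#   Rscript scripts/ystrnet.R stats    --input assigned.tsv --out DIR

suppressMessages(library(ystrnet))
suppressMessages(library(optparse))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) stop("usage: ystrnet.R <run|simulate|assign|network|date|stats> [options]")
cmd <- argv[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--input", type = "character", default = NULL),
  make_option("--preset", type = "character", default = "senior_zhuz"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--epsilon", type = "double", default = 0),
  make_option("--k", type = "integer", default = 3L),
  make_option("--out", type = "character", default = "ystrnet_out")
)), args = argv[-1])

need_input <- function() {
  if (is.null(opts$input) || !file.exists(opts$input))
    stop("missing upstream artifact: --input ", opts$input %||% "(unset)")
  read_samples(opts$input)
}
outdir <- function() {
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  opts$out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

switch(cmd,
  run = {
    cfg <- read_run_config(opts$config)
    cfg$seed <- opts$seed
    cfg$out_dir <- outdir()
    invisible(run_pipeline(cfg))
  },
  simulate = {
    pre <- switch(opts$preset,
                  senior_zhuz = senior_zhuz_preset(),
                  three_founder = three_founder_preset(),
                  stop("unknown preset: ", opts$preset))
    d <- simulate_clans(pre$clans, pre$lineages, seed = opts$seed)
    write_samples(d, file.path(outdir(), "samples.tsv"))
    jsonlite::write_json(sim_truth(d), file.path(opts$out, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE)
  },
  assign = {
    d <- need_input()
    d <- assign_haplogroups(d)
    if (any(c2st_downstream_markers() %in% names(d)))
      d <- assign_c2_downstream(d)
    write_samples(d, file.path(outdir(), "assigned.tsv"))
  },
  network = {
    d <- need_input()
    net <- build_mj_network(d, epsilon = opts$epsilon, label = "clan")
    write_network(net, file.path(outdir(), "network.graphml"))
    cl <- extract_clusters(net, k = opts$k)
    readr::write_csv(cl, file.path(opts$out, "clusters.csv"))
  },
  date = {
    d <- need_input()
    net <- build_mj_network(d, label = "clan")
    cl <- extract_clusters(net, k = opts$k)
    dt <- date_clusters(net, cl)
    readr::write_csv(dt, file.path(outdir(), "tmrca.csv"))
    print(as.data.frame(dt))
  },
  stats = {
    d <- need_input()
    if (!"haplogroup" %in% names(d)) d <- assign_haplogroups(d)
    f <- hg_frequencies(d, "clan")
    readr::write_csv(f, file.path(outdir(), "haplogroup_frequencies.csv"))
    if (dplyr::n_distinct(f$group) >= 2) {
      print(glance(amova_fst(d, units = "clan")))
    }
    cat(sprintf("haplotype diversity: %.3f\n", haplotype_diversity(d)))
  },
  stop("unknown subcommand: ", cmd)
)
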