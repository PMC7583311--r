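Package: ystrnet
Title: Y-Chromosomal Clan Structure from SNP Haplogroups and STR Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of patrilineal clan structure from Y-chromosomal
    genotypes: hierarchical haplogroup assignment from SNP panels,
    haplogroup frequency profiling, median-joining networks of Y-STR
    haplotypes with founder-cluster extraction and jackknife stability,
    rho-statistic TMRCA dating with standard errors and confidence
    intervals, diversity and AMOVA-based F_ST statistics, Nei genetic
    distances and ordination (MDS, PCA, Ward clustering), plus a forward
    simulator of clan gene pools under the stepwise mutation model that
    provides ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
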