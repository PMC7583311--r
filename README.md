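# ystrnet

Y-chromosomal clan structure from SNP haplogroups and STR networks.

## What this is for

In patrilineal societies, clan membership travels down the same line as
the Y chromosome, so the male gene pool of a set of clans records their
founding history. The standard analysis of such data asks: which
haplogroups dominate each clan; do several clans share one recent
founder lineage; how old are those founder expansions; and does the
genetic structure match the genealogical tradition? `ystrnet` implements
that chain end to end for population geneticists working with Y-SNP +
Y-STR genotype tables:

* **Haplogroup assignment** — deepest confirmed clade on a hierarchical
  SNP tree (35-marker backbone and a C2*-ST downstream panel ship as
  editable TSV configs), with `C2-M217(xM48, M407)`-style annotation of
  tested-negative daughters and `F5481*` paragroup labels.
* **Median-joining networks** of 15-locus Y-STR haplotypes (DYS385a/b
  excluded): ε-relaxed minimum spanning network plus inferred median
  (Steiner) vectors, deterministic under a canonical node order;
  founder-cluster extraction by network geodesics; jackknife stability
  (adjusted Rand index under 10% omission).
* **Rho-statistic TMRCA dating** — `rho` = mean mutational distance to
  the founder, `sigma² = (1/n²) Σ l_e n_e²` over the genealogy, and
  `age = g·rho/(L·μ)` with the usual calibration μ = 2.1×10⁻³ per locus
  per generation, g = 30 years, 95% CI `g·(rho ± 1.96σ)/(L·μ)`.
* **Population statistics** — haplotype diversity `n/(n−1)(1−Σp²)`,
  one-level AMOVA F_ST under alternative clan-grouping schemes, Nei's
  standard genetic distance, classical MDS / PCA / Ward ordination with
  Newick export.
* **A forward simulator** of clan gene pools under the symmetric
  stepwise mutation model (star or branching growth, SNP profiles
  consistent with lineage membership, full ground truth), so every
  stage is testable without restricted human data.

Everything is tidyverse-shaped: sample tables are tibbles, results have
`tidy()`/`glance()` methods and `autoplot()` figures, and the stages
compose with the pipe.

## Worked example

Simulate a study-like dataset (eleven clans, ~420 men, three young
C2*-ST founder lineages plus clan-specific and background haplogroups),
then run the analysis stages:

```r
library(ystrnet)

pre <- senior_zhuz_preset()
d <- simulate_clans(pre$clans, pre$lineages, seed = 42) |>
  assign_haplogroups() |>
  assign_c2_downstream()

glance(hg_frequencies(d, "clan"))
#>   n_groups n_haplogroups n_samples
#> 1       11            12       420

c2 <- d[!is.na(d$F3796) & d$F3796 == "derived", ]   # the C2*-ST subset
haplotype_diversity(c2)
#> 0.8

net <- build_mj_network(c2, label = "clan")
net
#> <mj_network> 76 nodes (65 sampled, 11 median vectors), 92 edges, cost 80, 166 samples

cl <- extract_clusters(net, k = 3)
date_clusters(net, cl)
#>   cluster   n   rho sigma age_years ci_low_years ci_high_years
#>      H018 129 0.798 0.129       760          519          1002
#>      H057  32 0.875 0.221       833          421          1246
#>      H023   5 0.200 0.200       190            0           564

glance(amova_fst(d, units = "clan"))
#>     fst     n n_units
#>   0.268   420      11
```

Reading the output: 12 haplogroups across 11 clans; 166 men fall in the
C2*-ST clade, whose haplotype diversity (0.80) is moderate, as expected
for a young founder pool. The network condenses them to 65 distinct
haplotypes plus 11 inferred intermediates. The largest cluster (n = 129)
dates to ≈760 years with a 95% CI of ≈520–1000 — matching its true
simulated depth of 25 generations × 30 years = 750 — and the clan-level
AMOVA F_ST of 0.27 says about a quarter of haplogroup variation lies
between clans. `autoplot(net)` draws the network;
`ordinate(nei_distance(hg_frequencies(d, "clan")), "mds")` ordinates the
clans.

Real data enter through `read_samples("samples.tsv")` (TSV/CSV, one row
per man; DYS389 totals handled via `dys389_format = "total"`), and
`run_pipeline()` drives all stages from one YAML config, writing
frequency CSVs, a GraphML network, cluster membership, the dating table
and a JSON summary. A thin CLI wraps the same functions:

```sh
Rscript scripts/ystrnet.R simulate --preset senior_zhuz --seed 1 --out out/
Rscript scripts/ystrnet.R assign   --input out/samples.tsv --out out/
Rscript scripts/ystrnet.R date     --input out/assigned.tsv --out out/
```

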