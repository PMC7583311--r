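---
title: "Methods: Y-chromosomal clan structure, STR networks and rho dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-chromosomal clan structure, STR networks and rho dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrnet)
```

## The problem

Patrilineal descent groups — clans — transmit their membership along the
same line as the Y chromosome. In steppe populations with documented clan
systems, this makes the male gene pool a readable archive: each clan tends
to be a mixture of a few founder paternal lineages, and the age, sharing
and geographic spread of those lineages test genealogical traditions
against molecular data. `ystrnet` implements the standard analysis chain
for such a study, from per-sample genotype tables to founder-lineage ages:

1. **haplogroup assignment** from a hierarchical SNP panel,
2. **frequency profiling** of haplogroups per clan,
3. **median-joining networks** of Y-STR haplotypes within a focal
   haplogroup, with founder-cluster extraction and a jackknife stability
   check,
4. **rho-statistic TMRCA dating** of each cluster,
5. **population statistics**: haplotype diversity, one-level AMOVA
   F~ST~ under alternative grouping schemes, Nei distances, and
   MDS/PCA/Ward ordinations,
6. a **forward simulator** of clan gene pools under the stepwise
   mutation model, which provides ground truth for every stage.

## Data model

A dataset is a tidy tibble, one row per man: `sample_id`, `population`,
`clan`, one integer column per STR locus, one ancestral/derived column
per SNP marker. The default STR panel is the 17-locus Y-filer set;
networks and dating use the 15 single-copy loci (DYS385a/b excluded,
since their alleles cannot be assigned to a copy). DYS389 is stored as
the independent quantity `DYS389b = DYS389II − DYS389I`; the reader
accepts either convention via `dys389_format`, because published tables
differ and the raw total would double-count DYS389I in step distances.

Samples missing any of the 15 network loci are excluded from network and
dating stages (with a logged count) but retained for haplogroup
frequency profiling — an assignment needs only SNP calls.

## Haplogroup assignment

The 35-marker backbone tree and the C2*-ST downstream tree
(F3796/F8951 and the F5481 subbranches) ship as TSV configuration files
(`inst/extdata/`), with ISOGG-style topology and labels; they are
validated on load (unique markers, single root, acyclic). Assignment
walks from the root and returns the deepest node whose whole ancestor
chain is called derived. Missing calls are *untested*: they block
further descent but are never treated as negative. Tested-ancestral
daughters annotate the label — `C2-M217(xM48, M407)` style for the
backbone, a `*` paragroup suffix for downstream subclades (`F5481*`).
A derived call under an ancestral parent raises an error naming both
markers, since no tree-consistent genotype can produce it.

When downstream SNPs are unavailable, C2*-ST membership can be called
from STR haplotypes alone: a nearest-centroid rule with a step-distance
threshold (`c2st_motif()`, default `max_steps = 5` on 15 loci). The
shipped centroid is an **assumed** modal haplotype — the defining motif
is conventionally taken from prior literature and is not part of this
package's assays — so both centroid and threshold are configuration, and
the SNP route is preferred whenever F3796 calls exist.

## Median-joining networks

Haplotypes are condensed to unique repeat vectors with multiplicities.
The metric is the single-step (weighted Manhattan) distance: the minimum
number of mutations under stepwise mutation. Construction follows the
median-joining scheme:

* the ε-relaxed **minimum spanning network** links every pair whose
  distance exceeds the largest edge on their MST path by at most ε
  (ε = 0, the common software default, gives the union of all MSTs);
* for each triplet with at least two pairs linked, the coordinate-wise
  **median vector** is a candidate Steiner node, scored by its connection
  cost *d(u,m)+d(v,m)+d(w,m)*; each round inserts the candidates within ε
  of the minimal connection cost, but a candidate is kept only if the
  total connection cost (the MST length of the node set) does not
  increase — this keeps the cost trace monotone, a property the tests
  assert;
* after convergence, median vectors of degree ≤ 2 are pruned to a
  fixpoint.

Determinism: nodes are ordered lexicographically by repeat vector, all
ties (candidate order, Kruskal edge order) break on that order, and no
randomness enters the construction, so identical inputs give identical
networks.

Median-joining is a heuristic. On star-like configurations — a founder
with few-step descendants, the geometry the method is used for — it
reaches the brute-force minimal Steiner cost on every fixture we test.
On adversarial uniform-random lattice inputs it can exceed the optimum
by one step in roughly 1% of tiny instances; the property suite
therefore asserts the guaranteed bounds (Steiner optimum ≤ network cost
≤ sampled-MST cost) on random inputs and exact equality on star-like
corpora.

Clusters are extracted by assigning each sampled node to the nearest
seed by network geodesic. "Clearly visible" clusters on published
networks have no formal definition; nearest-seed geodesic assignment is
our concretization, with seeds either explicit (founder modal
haplotypes) or the k highest-multiplicity nodes. Ties go to the seed
nearer the global modal node, then lexicographic. Stability is checked
by the published recipe — omit 10% of samples, rebuild, re-extract —
quantified with the adjusted Rand index and per-cluster persistence.

## Rho dating

For a cluster with founder node *f*,
`rho = mean over sampled chromosomes of d(h_i, f)` along network
geodesics, and

σ² = (1/n²) Σ<sub>edges</sub> l<sub>e</sub> n<sub>e</sub>²

over the shortest-path genealogy from the founder (for a star this is
σ² = ρ/n). Ages convert as `age = g·rho/(L·mu)` with defaults
μ = 2.1×10⁻³ mutations per locus per generation, L = 15 loci,
g = 30 years, and a normal 95% CI `g·(rho ± 1.96σ)/(L·mu)` clamped at
zero. All four numbers are parameters (`dating_params()`), never
constants, so switching to an evolutionary rate or a different
generation time is one argument.

The founder of each cluster defaults to its highest-multiplicity
(modal) node — the natural choice for a star expansion, where most
descendants still carry the founder haplotype — and is overridable.
`rho_tmrca()` offers the direct (non-network) variant: mean step
distance to a modal or supplied founder with the star variance, which
is what the large-replicate recovery simulations use.

**Known limitation (depth bias).** Step distance cannot see a pair of
mutations at the same locus that cancel (+1 then −1), so rho
underestimates the true mutation count increasingly with depth: ~0.4%
at 10 generations, ~2.4% at 25, ~5% at 50 under the default rate. In
our recovery simulations (n = 100 chromosomes, 500 replicates) the 95%
CI covers the true age ≈95% of the time at 25 generations but only
≈90% at 50 generations, where the bias is no longer negligible against
the CI width. This is a property of rho dating itself, not of the
implementation; the acceptance suite asserts the 92–98% coverage band
at T ∈ {10, 25, 50} and the T = 50 case fails it for exactly this
reason. Depths around 25 generations — the regime the package targets —
are unaffected in practice.

## Population statistics

* **Haplotype diversity**: `HD = n/(n−1)·(1 − Σ p_i²)`.
* **AMOVA**: one level, pairwise distance 0/1 on haplogroup identity
  (an STR-step-squared option exists). Sums of squares follow the
  standard decomposition; negative among-unit variance estimates are
  truncated at zero for F~ST~ (the raw component stays in the table).
  Merged grouping schemes (e.g. a pooled "core" of clans vs. each clan
  separate) are expressed as named clan→unit maps. Hierarchical
  (two-level) AMOVA and permutation p-values are out of scope; the
  comparison of schemes uses point estimates.
* **Nei standard distance** over haplogroup frequencies:
  `D = −ln( Σx_iy_i / √(Σx_i²·Σy_i²) )`, `Inf` for zero-overlap pairs.
* **Ordination**: classical metric MDS (Torgerson double-centering) —
  chosen over iterative non-metric MDS for determinism — PCA on
  centered frequencies, and Ward (ward.D2) clustering with Newick
  export. Degenerate (flat) geometries are padded with zero axes rather
  than erroring, since fully identical profiles are legitimate in
  simulated data.

## The simulator

`simulate_lineage()` draws each sampled chromosome as a descendant of a
founder haplotype: per generation and locus a mutation occurs with
probability μ and steps ±1 with equal probability — the symmetric
single-step model, with no multi-step mutations and no allele-range
bounds (a documented simplification; both effects are second-order at
the depths simulated). Growth is either `star` (independent lines, the
classic rapid-expansion approximation) or `exponential` (a forward
branching process calibrated so the expected tip count reaches the
target, giving shared internal branches). SNP profiles are spelled out
derived along the founder's haplogroup path and ancestral elsewhere.
Every sample's generating lineage, mutation-event count and depth are
recorded as ground truth beside the table.

`senior_zhuz_preset()` fixes the study conditions the package is built
around: eleven clans, ~420 men, a young C2*-ST founder trio (depth 25
generations ≈ 750 years; the dominant "gamma" lineage carried by a core
of four clans at 40–60%, an "alpha" F5481* lineage concentrated in one
non-core clan, a minor "beta" F8949 lineage), clans fixed for other
haplogroups (80% N1a1a, 75% J1, 55% Q, 35% G2), and older background
lineages (J2, R1a, O2, R1b, I1, C2-M48, C2-M407, depths 40–60
generations) at realistic minor frequencies. The compositions were set
once from the published clan profiles this design emulates and are not
tuning knobs. `three_founder_preset()` is the reduced validation
preset: three clans, one star lineage each (40 samples, depth 25),
founders ≥8 steps apart — separated enough that cluster recovery is
expected to be clean, which is what makes it useful as ground truth for
the network and jackknife checks.

What the simulator does *not* emulate: locus-specific mutation rates,
multi-step mutations, back-migration between clans, genotyping error,
and population growth histories beyond the two growth modes. Passing
tests therefore demonstrate correctness of the machinery under the
stated model, not robustness to every feature of real forensic data.

## Problem sizes and numerical choices

The test and acceptance runs use: 500 replicates × 100 chromosomes for
rho recovery at each depth; 100 jackknife replicates on the 120-sample
three-founder preset; ~60-sample C2*-ST networks in the full preset
run. Comparisons of floating-point costs use a 10⁻⁹ slack; repeat
counts and step distances are integers throughout. The Kruskal MST
inside the network builder is the package's own (deterministic
tie-breaking is load-bearing); tests cross-check its costs against an
independent graph library implementation.

## Reproducibility

Every stochastic entry point takes an explicit seed; `run_pipeline()`
seeds once from its config and re-running with the same config and seed
produces byte-identical JSON summaries (asserted in the tests). The
acceptance script (`scripts/acceptance.R`) recomputes all headline
quantities from scratch for any seed.
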