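---
title: "Biclustering by extremal-set overlap: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biclustering by extremal-set overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuba)
```

## The model

In heterogeneous cohorts — tumour expression data being the motivating case —
small sets of genes can be aberrantly co-expressed in small subsets of
samples. Global similarity measures (Pearson, Spearman) average over the
whole cohort and dilute such signals. The proximity measure implemented here
asks a narrower question: for two genes, do the samples at the extremes of
their expression profiles coincide?

For each gene we take its **extremal set**: the `k = round(x · N)` samples
(half-up rounding) with the highest (direction `"high"`) or lowest
(`"low"`) expression, where `x` is the percentile fraction and `N` the
cohort size. If two genes' extremal sets of sizes `k1`, `k2` share `m`
samples, the overlap count under independence is hypergeometric, so the
proximity of the pair is the one-sided Fisher's exact p-value

$$P(X \ge m) = \sum_{j \ge m} \frac{\binom{k_1}{j}\binom{N-k_1}{k_2-j}}{\binom{N}{k_2}}.$$

Because the measure uses only set membership, it is insensitive to rank
shuffling inside the extremal sets, does not model the expression
distribution, and needs no pre-specified sample groups.

Pairs passing the significance cut-off become edges of a co-expression
graph whose edges "are" the shared samples. Biclusters are carved out of
this graph:

1. **Triangle pruning.** Edges belonging to no triangle are removed
   iteratively until every surviving edge lies in at least one 3-clique.
   This discards isolated pairwise coincidences.
2. **Seeding.** All maximum cliques are enumerated (Bron–Kerbosch, via
   igraph). If the maximum clique is not unique, equally large cliques with
   overlapping gene sets are merged into one seed; disjoint ones are left
   for later iterations.
3. **Trimming.** All edges incident to seed genes are removed and the graph
   re-pruned; steps 2–3 repeat until no edges remain. Seeds are therefore
   pairwise disjoint in genes.
4. **Expansion.** Each seed is re-introduced into the *pruned* (not
   trimmed) graph, and every node adjacent to ≥ 2 seed genes is added in a
   single pass. The bicluster's edges are the induced edges on the final
   gene set, its samples the union of the edges' shared-sample sets, and
   each gene's degree its induced edge count (high-degree genes are
   candidate drivers).

### Scoring

Membership and scoring are kept separate: scores never alter membership.
For a bicluster `B` with `m` samples, each member gene's top-`m` set is
tested for hypergeometric enrichment in `B`'s samples; each member sample
`s` is tested through the set `G_s` of all genes in the dataset carrying
`s` in their top-`m`, against `B`'s gene set in the universe of all genes.
Gene tests are BH-adjusted pooled across all biclusters of the run, sample
tests likewise — the pooled family is the conservative choice and makes
scores comparable between biclusters. The quality index is

$$Q(B) = \min\left(\text{frac. genes with FDR} < 0.05,\ \text{frac. samples with FDR} < 0.05\right) \in [0, 1].$$

## The two tunable parameters

* **Percentile `x`** (default 0.05, fraction of the cohort): controls the
  granularity of the heterogeneity probed. Smaller sets make complete
  overlaps more significant (for `N = 200`, a complete overlap of two
  top-5% sets has `p = 1/\binom{200}{10} ≈ 4.45·10⁻¹⁷`, while a 10-of-20
  overlap at 10% sets is only ≈ 9.2·10⁻⁷) but also easier to hit by
  chance; `k` is floored at 2.
* **Overlap significance cut-off** (default FDR ≤ 1e-8): decides which
  pairs enter the graph. BH adjustment is computed over the full family of
  `G(G−1)/2` pairs, with zero-overlap pairs entering at `p = 1` — this is
  reproducible and independent of sparsity tricks, and such pairs can never
  survive the cut-off anyway. `tuning_curve()` tabulates edges, genes and
  samples in the graph over a decade grid, and `suggest_cutoff()` applies
  the growth heuristic: choose the least stringent cut-off whose relaxation
  by one decade adds 40–60% more edges; if none qualifies the cut-off with
  growth ratio closest to 1.5 is returned, flagged approximate.

`permutation_null()` calibrates the machinery: permuting sample labels
independently per gene destroys all pairwise structure, and at stringent
cut-offs no adjusted pair should remain significant.

## Numerical choices

* Tails are computed by `phyper` in log space, so extreme values
  (`1e-165` and beyond) are exact to double precision rather than
  underflowing partial sums. The test suite checks agreement with an
  explicit binomial-coefficient tail sum to `1e-12` relative error,
  exhaustively for all `N ≤ 60`.
* Ties at the extremal boundary are broken by canonical (column) sample
  order under a stable sort, making every downstream step deterministic;
  heavily tied data (zero-inflated counts in the low direction) can
  optionally be guarded with the `min_distinct` filter, which drops genes
  whose boundary tie group would overflow the set.
* Where several disjoint maximum-clique components tie, the component
  containing the lexicographically smallest gene identifier is seeded
  first — a pure tie-break for determinism, with no effect on the final
  set of seeds.
* Expansion is a single pass over candidates (≥ 2 *seed* neighbours, not
  bicluster neighbours): iterated expansion could chain unrelated modules
  together through shared hubs, defeating the locality of the seeds.
* Trimming removes seed-incident *edges* only; any node isolated by this
  is dropped by the subsequent re-pruning.
* Degenerate inputs degrade gracefully: fewer than 3 genes passing the
  cut-off yields an empty graph with a warning and an empty collection;
  an empty `G_s` in sample scoring yields `p = 1`; `k < 2` is an error
  instructing a larger percentile or cohort.

## Downstream analyses

* `compare_collections()` matches two runs by hypergeometric gene-set
  overlap (BH over all cross pairs; default match threshold FDR < 0.001).
* `categorical_enrichment()` tests bicluster samples against any
  categorical annotation (subtype, grade, node status) with the one-sided
  Fisher's exact test, BH-adjusted across biclusters × categories.
* `cna_enrichment()` tests, per gene, whether copy-number-positive samples
  concentrate in the bicluster, and combines the per-gene p-values with
  Fisher's method (`χ² = −2Σ ln p` on `2k` df). Call positivity defaults
  to `±1` on GISTIC2-style calls — the threshold is configurable since
  conventions differ. The cohort-wide sample set is used as the test
  background.
* `classify_proximal()` calls a bicluster *proximal* when ≥ 80% of its
  annotated genes lie on one chromosome within a 25 Mb window. These knobs
  operationalize what is otherwise a visual cytoband judgment; they are
  reported alongside every call and should be treated as a screen, not a
  verdict.
* `membership_and_hamming_clustering()` clusters the bicluster × sample
  binary membership matrix by Hamming distance (equivalently Manhattan on
  0/1 vectors) with average linkage by default — the linkage is recorded
  in the output since no principled default exists.
* Survival comparisons are deliberately delegated: the membership tables
  are written in a form any survival package can consume.

## The synthetic benchmark

`generate_background()` draws i.i.d. per-gene baselines with gene-specific
means (log-normal intensities, or negative-binomial counts on
`log2(x+1)`), and `implant()` adds a block shift so that a gene set becomes
co-extremal in a chosen sample set. Shifts are additive on the provided
scale — on log-scale data an additive shift is a fold change — rather than
rank surgery, so the tie-breaking code paths are exercised too. Effects can
be specified in expression units or in multiples of each implanted gene's
background standard deviation; the latter is used by the default benchmark
because under a log-normal background the absolute spread varies strongly
across genes, and a fixed-unit shift would make an implant's strength
depend on which genes it happened to land on.

The default benchmark (`default_benchmark()`) is 1,000 genes × 200
samples, lognormal background, 3 disjoint implants of 20 genes × 10
samples at +6 background SDs, seed 42 — large enough that the 5% extremal
sets have 10 members and BH families are realistic, small enough for
seconds-scale runs. At these settings all three implants are recovered
with gene and sample Jaccard ≥ 0.8, implanted genes score FDR < 0.001,
and ≥ 95% of implanted samples score FDR < 0.001.

What the generator does *not* emulate: library-size variation, mean–
dispersion trends, batch structure, or correlated background genes. The
algorithm is rank-based on extremes, so distributional realism is
secondary — but a pass on this benchmark shows correct mechanics and
calibration, not performance on real tumour cohorts, where extremal sets
of co-regulated background pathways produce many more edges than an
i.i.d. background does.

Test and benchmark problem sizes (500 × 200 permutation null with 10
iterations, 1,000 × 200 recovery benchmark, random graphs of 14–30 nodes
for the structural properties, exhaustive oracle grids up to `N = 60`)
were chosen so the whole suite runs in well under a minute while keeping
every family of tests at a size where failures are informative.

## Known limitations

* Exact maximum-clique search is NP-hard; graphs built at overly lenient
  cut-offs can make seeding expensive. The tuning heuristic exists
  precisely to keep the graph in the regime where exact search is cheap.
* Genes are dropped, never merged: duplicate identifiers (e.g. several
  probes per gene) are surfaced as errors rather than collapsed, since no
  principled merge rule is universal.
* In the low direction, zero-inflated data make extremal membership
  tie-dominated; use `min_distinct` or pre-filter low-expression genes.
* A bicluster's sample set is the union of its edges' shared-sample sets;
  no alternative aggregation (e.g. intersection or weighted membership) is
  offered.
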