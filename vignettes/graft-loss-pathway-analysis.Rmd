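---
title: "Methods: pathway activation, crosstalk centrality and propagation-based etiology ranking"
author: "glpapnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway activation, crosstalk centrality and propagation-based etiology ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glpapnet)
```

# The analytical problem

The package addresses a late, biopsy-inaccessible transplant failure
observed through peripheral-blood transcriptomes of two subjects — one
losing the graft, one stable — each sampled at four matched timepoints
(t1 before transplantation, t2 stable, t3 at the onset of graft loss, t4
after overt failure). There is one sample per subject per timepoint: no
replication, so every statistic must draw its null from somewhere other
than biological replicates. The pipeline answers two questions: *which
pathways were activated during the graft-losing period*, and *which of a
set of candidate etiologies best explains the expression change*.

# Pathway activation and the GLPAP rule

For a comparison of two samples, genes with abundance below
`minExpression` (default 1, the usual TPM-scale floor) in *either* sample
are removed — with single samples in both arms, near-zero denominators
otherwise produce unbounded fold changes. Remaining genes get
`log2(a/b)`.

A pathway's activation statistic is the mean log2FC of its member genes
present in the profile. Its one-sided p-value for up-regulation comes
from a competitive permutation test: `nPermutations` (default 999) random
gene sets of the same size are drawn from the profiled universe and
`p = (1 + #{perm mean ≥ observed}) / (nPermutations + 1)`. The add-one
correction keeps p strictly positive and valid at any number of
permutations; an `exact = TRUE` mode enumerates all subsets for small
universes and is the reference the sampled mode is tested against. This
test is a deliberately transparent stand-in for time-series pathway
impact analysis tools: downstream stages consume nothing but a
per-pathway one-sided p-value, so any statistic honoring that contract
can sit here, and a permutation test is the one whose null can be checked
exactly.

A pathway is a **GLPAP** (graft-loss-period activated pathway) when it is
up-regulated with `p < alpha` (default 0.05, *strict* inequality) in both
the within-subject comparison (case t3 vs t2) and the between-subject
comparison (case vs control at t3). The two comparisons share the case-t3
sample, so their statistics are positively correlated under the null
(about 0.5 for equal noise variances); the intersection therefore filters
less than `alpha^2` naively suggests — roughly 1.3% of null pathways
rather than 0.25%. The test suite checks the observed null rate against a
Monte-Carlo estimate that models this correlation, not against the
independence value.

# Category enrichment

Categories are treated as a partition (each pathway exactly one
category). For each category the 2×2 table (GLPAP × in-category) is
tested with the one-sided hypergeometric tail `P(X ≥ a)` — Fisher's exact
test with alternative "greater", computed via `stats::phyper` and
cross-checked in the tests against exhaustive enumeration of all tables
with N ≤ 40. Raw p-values are reported sorted ascending, ties broken by
category name; no multiple-testing correction is applied across
categories, since the output is a ranked descriptive table rather than a
family of decisions. Users who need decisions should apply `p.adjust`.

# Crosstalk network and central pathways

Two GLPAPs crosstalk with weight = (shared member genes) + (PPI edges
with one endpoint exclusive to each pathway). An edge requires weight ≥
`minCrosstalk` (default 1); pathways left isolated are dropped. The rule
is a transparent stand-in for published pathway-interaction constructions
whose internals are not specified at this level; what downstream stages
need is only a pathway graph on which degree and closeness are
meaningful.

Closeness is Wasserman–Faust component-aware:
`C(v) = (r/(n−1)) · (r/S)` with `r` reachable nodes and `S` their summed
hop distances, reducing to `(n−1)/S` on a connected graph. This keeps
values comparable when the pathway graph is disconnected, which happens
routinely when a few GLPAPs have no crosstalk partner. One caveat worth
recording: with this normalization, adding an edge that bridges to a
large distant component can *decrease* a node's closeness (reach grows,
but summed distances can grow faster), so monotonicity under edge
addition holds only within a connected graph — the property test is
scoped accordingly.

A pathway is central when closeness *and* degree strictly exceed the
arithmetic means over **all** nodes in the graph; with `restrictTo` the
selection (not the cutoff computation) is limited to one category. Strict
inequality matters: the bundled worked example
(`immunePathwayMetrics()`) has a pathway at closeness 0.46789 against a
cutoff of 0.4669 — selected — and another at degree 8 against 8.65 —
rejected — and reproduces exactly a three-pathway selection from eight
immune-system candidates.

# Network propagation and etiology ranking

Each candidate etiology is a seed-gene set. Influence is spread by random
walk with restart, `s ← (1−r)·W·s + r·s0`, with `s0` uniform over the
seeds. Defaults: restart probability `r = 0.5` (the common choice in the
gene-prioritization literature; results are insensitive over 0.3–0.7
since only ranks are used), degree-symmetric normalization
`W = D^{−1/2} A D^{−1/2}` (the genomics default; a column-stochastic,
mass-conserving mode is available), `tol = 1e-8` on the L1 change,
`maxIter = 10000`. The iteration is a contraction with factor `(1−r)`, so
the fixed point equals the direct solve `r(I − (1−r)W)^{−1} s0`; the test
suite verifies agreement to 1e-8 against a dense solve.

The DEG profile is the filtered log2FC of case vs control at t3, ranked
descending (signed by default — the analysis is framed around
up-regulation; an absolute-value option exists), ties mid-ranked. The
evaluation statistic is the Pearson correlation of the two *rank*
vectors restricted to shared genes (equivalently Spearman on scores),
with a parametric p from the t-distribution, plus an optional top-k
variant (`topK = 100`) over the k most-influenced genes, boundary ties
broken by gene id.

Significance comes from random seed simulation: `nSim` (default 1000)
random seed sets of the same size, each propagated and correlated, and
`empirical p = (1/N) · #{c_j > c_ref}` — the literal strict-exceedance
fraction, so 0 is attainable; a positively biased add-one variant is
available behind `correction = "add_one"`. The random sampler is uniform
over network genes by default; a degree-matched sampler (log2-degree
bins of the reference seeds, nearest non-empty bin fallback) is provided
because uniform sampling under-represents hubs.

Whole-network rank correlations in this setting are small by
construction: when ~5% of genes carry differential signal, even a
perfectly causal seed set yields coefficients of a few hundredths. The
discriminating quantity is the empirical p against size-matched random
seeds, not the absolute coefficient.

# The synthetic-data generator

`simulateGraftLossDataset()` emulates the study conditions: 2 subjects ×
t1..t4; defaults of 6,780 genes, 287 pathways in 17 categories
(KEGG-scale), pathway sizes 10–80; a preferential-attachment PPI with 17
edges per added node (≈118k edges on ≈6.8k nodes, curated-interactome
density); 5 hypotheses with seed sizes 10/9/8/10/9, the fourth causal.

Choices that matter, and why:

* **Expression**: per gene one baseline mean log-expression
  (`N(baselineLogmean = 3, baselineLogsd = 1)`) shared across samples,
  plus independent per-sample log-noise (`noiseLogsd = 0.25`). Log-normal
  abundance makes the log2FC between samples zero-centered noise under
  the null, which is exactly what the activation statistic assumes. The
  real study data's distributional details are unknown; this is a
  stand-in, not a claim.
* **Activation**: member genes of the planted pathways are multiplied by
  `activationFold` (default 4) at exactly one (subject, timepoint) cell —
  the case subject at t3 — so both GLPAP comparisons see the signal.
  `activationFold = 1` produces a null dataset with the DE-gene book-keeping
  intact.
* **Planted pathways share one category** (drawn from a single category
  with enough members), so category-enrichment recovery is testable.
* **PPI**: Barabási–Albert preferential attachment for the global
  scale-free topology, *plus one random spanning path through each
  pathway's members*. Pure preferential attachment has no community
  structure, which makes pathway members network-scattered — unlike real
  interactomes, where functional-module cohesion is the very premise of
  crosstalk and propagation analysis. The added intra-pathway edges give
  each pathway a connected footprint while leaving the degree
  distribution heavy-tailed.
* **Causal seeds** are chosen among direct PPI neighbors of the DE genes
  (never DE genes themselves, so propagation must add value over naive
  overlap) by greedy maximum coverage penalized by the square root of
  candidate degree: unpenalized greedy picks mega-hubs whose
  neighborhoods contain DE genes only at the background rate, which
  encodes no etiology-specific signal. If the penalized pick covers less
  than half of the DE genes, plain coverage-greedy is used instead; the
  generator contract is that the seeds reach at least half of the DE
  genes in one hop. Non-causal seed sets are drawn uniformly from genes
  outside the DE genes and their 1-hop neighborhood.

What the generator does *not* emulate: sequencing depth and library-size
effects, batch structure, isoform complexity, correlated co-expression
beyond pathway membership, and literature-derived seed lists. Passing
recovery tests therefore demonstrates that the pipeline's inference is
sound when its assumptions hold — not that those assumptions hold for any
particular real dataset.

# Numerical and degenerate-input conventions

* Permutation and empirical p-values use fixed integer seeds wherever
  exposed (`rngSeed` arguments); identical configs give byte-identical
  pipeline outputs.
* A pathway with no gene in the profile is flagged untestable and
  excluded from selection rather than erroring.
* An empty GLPAP set yields all-1 enrichment p-values and an empty
  crosstalk graph, each with a warning.
* Seeds absent from the PPI are dropped with a warning; an empty mapped
  seed set is an error.
* Permutation-mean comparisons use a 1e-12 tolerance so the observed
  subset always counts itself despite floating-point summation order.
* Top-k and frontier ties are broken by gene id; ranks use mid-ranks.

# Problem sizes used by the test suite

The packaged tests run the recovery study at 2,000 genes, 50 pathways
(sizes 10–30) in 10 categories, 5 planted pathways at fold 4, PPI
attachment 17, over 50 replicates with 199 activation permutations and
25 empirical-p simulations per hypothesis; null calibration uses a
fold-1 dataset of 1,500 genes / 50 pathways (999 permutations) and 200
empirical-p replicates on a 150-node network with a 20-point lattice.
These sizes keep each property estimable with tight Monte-Carlo error
while the whole suite stays interactive; the acceptance script runs the
same design with the full 999 permutations and 1000 simulations.

# Known limitations

* Two subjects, one sample per cell: all p-values are permutation- or
  simulation-based and condition on the observed profiles; nothing here
  estimates biological variance.
* The activation test is competitive (against random gene sets), so
  heavy inter-pathway gene sharing correlates pathway p-values; the
  GLPAP intersection inherits the comparison correlation noted above.
* Crosstalk weights are unnormalized counts; large pathways get more
  edges. The centrality stage partially absorbs this because cutoffs are
  network-wide averages.
* The empirical p has resolution 1/N and no continuity correction in its
  literal form; use `correction = "add_one"` when downstream thresholds
  require strictly valid p-values.
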