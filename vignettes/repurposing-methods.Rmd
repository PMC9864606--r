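---
title: "Methods: pathway-level connectivity mapping for single-cell drug repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-level connectivity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`screpurpose` chains six stages, each exposed as plain functions so any
stage can be run, inspected or replaced in isolation:

1. **QC** — cell filters (detected genes, mitochondrial and hemoglobin
   content), then gene filters, then normalization.
2. **Cell typing** — marker-score annotation of individual cells.
3. **Pseudobulk** — geometric-mean aggregation per (cell type,
   condition).
4. **Pathway activation** — per-pathway PAL from case-to-normal ratios.
5. **Query construction** — up/down gene lists from the top activated
   and inhibited pathways.
6. **Connectivity ranking** — reverse-mode scoring against a drug
   signature bank, then cross-cell-type aggregation.

A synthetic-data module generates every input with known ground truth;
the whole chain is deterministic given its inputs and seeds.

## QC and normalization

Cells are kept when their detected-gene count lies in
`[min_features, max_features]` (defaults 200 and 2500, both inclusive)
and their mitochondrial and hemoglobin count percentages are *strictly*
below 10%. Mitochondrial genes are recognized by the case-insensitive
symbol prefix `MT-`, hemoglobin genes by `^HB[ABDEGMQZ]` (which matches
the hemoglobin subunit family but not e.g. `HBEGF`). Genes are then kept
when detected in at least `min_cells = 3` cells. The order is fixed —
cells first, then genes — because gene detection counts change after
cell removal; a regression test pins this order on a fixture where the
two orders disagree.

Normalization is library-size scaling with a log1p transform:
`value(g, c) = log(1 + 1e4 * count(g, c) / total(c))`. Regularized
count-model normalization (SCTransform-style) and cross-donor
integration are deliberately *not* part of this pipeline: the downstream
pathway statistic consumes only case/control ratios of per-gene
aggregates pooled over donors, for which library-size scaling preserves
a planted fold change, and integration is an embedding-level correction
for clustering, which this pipeline does not perform. The substitution
is recorded in every run manifest.

## Marker-score cell typing

Rather than clustering cells and annotating clusters, each cell is
scored directly against every marker set: `score(t)` is the mean of
per-gene z-scores (computed across all cells) over the markers of type
*t*. The cell takes the argmax label when the margin to the second-best
score is at least `min_margin = 0.1` (in z-score units), otherwise it is
`unassigned`; exact ties resolve to the lexicographically smallest label
and hence to `unassigned` whenever a positive margin is required.
Zero-variance genes contribute z = 0, so adding an all-zero gene never
changes an assignment. Direct scoring makes ground-truth recovery
testable and removes a graph-clustering dependency that is peripheral to
the pathway-to-drug chain; the cost is that cell types not described by
any marker set can never be discovered, which is acceptable here because
the queries are built per *known* cell type.

Cluster marker detection (`find_markers`) is one-vs-rest: per gene, a
two-sided Wilcoxon rank-sum test of in-cluster versus all other cells,
`log2FC = log2((mean_in + 1e-9) / (mean_out + 1e-9))`, and nonzero
fractions per group. Reported genes satisfy `log2FC >= 0.25`,
`p <= 0.01` (raw by default; a BH-FDR switch exists but is off because
the threshold is conventionally applied raw) and
`max(pct_in, pct_out) >= 0.3`. When both groups have at most 8 cells the
p-value is computed by exact enumeration of all C(n+m, n) rank
assignments — defined as `P(|W - E[W]| >= |w_obs - E[W]|)` under the
permutation null, which handles ties exactly — because the standard
exact routine in `stats::wilcox.test` declines tied data; larger groups
use its tie- and continuity-corrected normal approximation.

## Pseudobulk, CNR and PAL

The pseudobulk profile of a (cell type, condition) group is
`gm(g) = exp(mean over cells of log(1 + value(g, c)))`. The +1
pseudocount inside the log keeps genes that are zero in every
contributing cell well-defined at `gm = 1`, which propagates to a
case-to-normal ratio `CNR(g) = gm_case(g) / gm_control(g)` of exactly 1
— a neutral log-ratio — rather than an indeterminate 0/0.

The pathway activation level is

`PAL(P) = 100 * sum(ARR(g) * log2 CNR(g)) / sum(|ARR(g)|)`

over the pathway genes present in the filtered matrix (absent genes are
skipped and the count of used genes reported, so thin pathways are
visible). ARR is the activator/repressor role of the gene within the
pathway (+1/-1; 0 excludes a gene from both sums). This is the
activator/repressor-weighted mean log case-to-normal ratio of
geometric-mean profiles, scaled by 100; proprietary refinements of
published PAL implementations (per-gene importance factors) are not
reproduced. Log base 2 is used consistently with the marker fold-change
threshold; the base only rescales PAL and never changes a ranking.
Useful consequences, all enforced by tests: PAL is exactly antisymmetric
under swapping case and control, zero on identical profiles, bounded by
`100 * max |log2 CNR|`, and reduces to `100 * mean(log2 CNR)` when all
genes are activators.

Per cell type, the top `k = 10` pathways with the largest PAL *among
those with PAL > 0* form the activated list (descending), and the top
10 with PAL < 0 the inhibited list (ascending); ties break by pathway
ID. The sign gate matters: reverse-mode querying needs directional
lists, and a pathway with PAL = 0 carries no direction. Both lists may
therefore be shorter than 10.

## Query signatures

The up side of a cell type's query is the union of the genes of its
activated pathways, the down side the union over inhibited pathways. A
gene landing in both unions is assigned to the side matching the sign of
its own log2 CNR — keeping the query consistent with the measured
direction — and dropped when that log-ratio is exactly 0. Sides are
ordered by descending |log2 CNR| and truncated to `max_per_side = 2000`,
a cap reflecting typical signature-search query limits. Genes are plain
set-union members; repeated membership across pathways is recorded as
provenance but not weighted.

## Connectivity scoring

Two engines score a bank experiment against a query:

* **Interception (set-overlap) score.** Reverse mode:
  `(|q.up ∩ d.down| + |q.down ∩ d.up|) / (|q.up| + |q.down|)`; mimic
  mode swaps the matched sides. The score is in [0, 1], reaches 1 only
  for a complete reversal, and is monotone: adding a query-up gene to a
  drug's down set never lowers the reverse score.
* **Weighted KS connectivity.** The classic running-sum enrichment of
  each query side in an ordered gene list (+1/s at hits, -1/(N-s) at
  misses; the internal walk uses an integer scaling by `s·(N-s)` so the
  extremum is exact in floating point). On an exact magnitude tie
  between the maximal and minimal excursions the positive one is taken,
  fixed for determinism. Connectivity = (ES(up) - ES(down))/2; strong
  reversals are near -1, so reverse-mode ranking sorts ascending.
  Because the bank stores gene *sets*, a set-valued experiment is
  embedded into an ordered list deterministically — up genes first, the
  rest of the bank's gene universe in the middle, down genes last, each
  block alphabetical — before KS scoring.

Ranking is experiment-level (one molecule may hold several ranks via
different doses or cell lines), sorted by score with ties broken by
experiment ID; `unique_molecules = TRUE` switches truncation to the
first occurrence per molecule. No minimum-overlap cutoff is applied: a
zero-scoring experiment simply never reaches the top of a list that
contains any positive score.

## Aggregation across cell types

Occurrence counts are experiment-level by default (a molecule hit by two
experiments within one cell type counts twice), with a molecule-level
mode exported alongside since display conventions differ; "occurs more
than five times" is a display threshold (`count >= 6` flagged), never a
selection filter. Cell-type intersections use exact-membership (UpSet)
semantics: every molecule belongs to exactly one group, the groups
partition the union, and their sizes sum to the unique-molecule count —
an identity asserted on every run. The unique count and the
common-to-all intersection are reported per run.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: a
multi-donor case/control cohort with marker-structured immune cell types
and condition-specific shifts concentrated in chosen pathways of chosen
cell types.

* Counts are negative binomial with a single global dispersion
  (`variance = mu + dispersion * mu^2`), the simplest model with
  scRNA-seq-like overdispersion. Defaults: baseline mean 0.5 per gene
  per cell and dispersion 0.3, giving ~370 detected genes per cell on a
  1000-gene universe — a realistic sparsity regime that clears the
  default QC window.
* Six case and six control donors, five immune cell types, 86 cells per
  type per donor: > 500 cells per (type, condition), enough for stable
  pseudobulk ratios.
* Markers are a mean-fold elevation (default 8x) on 10 genes per type,
  not exclusive expression, so marker-score annotation is a nontrivial
  but solvable task.
* Planted effects multiply the case-cell means of one pathway's genes in
  one cell type by `2^log2_fold`; the default effect size
  `log2_fold = 2` is a calibration choice (no effect-size information
  exists for the motivating disease contrasts), chosen as a clearly
  biological yet not trivial shift.
* ~2% of cells are generated "low-quality" with a 40x boost on `MT-`
  gene means, so the mitochondrial filter has real work to do.
* The drug bank contains exact reversers — DOWN sets drawn from the
  planted up-pathway genes of the targeted cell type, empty sides padded
  with random non-planted genes (pad fraction recorded in bank
  metadata) — among decoys drawn from non-planted genes. A corruption
  fraction can degrade reversers into harder partial positives; the
  default is 0 (exact reversal).

What the generator deliberately does **not** simulate: ambient RNA,
doublets, batch and donor random effects, UMI-level noise, gene-gene
correlation beyond the planted block structure, and realistic pathway
databases. Passing tests therefore demonstrate that the pipeline's
logic recovers a planted pathway-level signal under clean overdispersed
noise — not that it would rank real drugs correctly from real patient
data, where normalization artifacts, annotation ambiguity and bank
quality dominate.

## Numerical and design choices

* Gene identifiers are upper-cased on construction everywhere (matrix,
  pathways, markers, banks, queries), so all set operations are
  case-insensitive by construction.
* Strict versus non-strict bounds follow the printed conventions:
  feature bounds inclusive, contamination percentages strictly below
  threshold.
* All tie-breaks are lexicographic (cell-type labels in annotation,
  pathway IDs in top-k, experiment IDs in ranking), making every output
  a total order and reruns byte-identical.
* Pathways with no evaluable gene return `PAL = NA` and are excluded
  from ranking rather than raising an error, since a thin pathway is a
  data property, not a caller mistake.
* Every generator is a pure function of its seed via an isolated RNG
  scope; the pipeline itself draws no random numbers.

## Problem sizes

The test suite and the acceptance script run entirely at desk scale,
chosen so the full planted-recovery study stays light while keeping
> 500 cells per (type, condition): 1000 genes x 5160 cells per cohort,
40 pathways of 20 genes, a 205-experiment bank, and 20 independent
seeds for the recovery study. Unit fixtures are far smaller (tens of
cells) and verified against closed forms or exhaustive-enumeration
oracles.

## Known limitations

* The interception score is this package's own definition of
  "ranked by intersection of query and signature gene sets"; external
  signature-search services do not publish their exact statistic, so
  absolute scores are not comparable across tools (rankings are the
  meaningful output).
* Single pooled pseudobulk per condition: no per-donor replicates, hence
  no uncertainty estimate on PAL. With six donors per arm a donor-level
  jackknife would be a natural extension.
* One-vs-rest marker detection only; no pairwise contrasts, no
  subclustering of closely related cell states.
* The KS engine's set-to-list embedding is a convention, adequate for
  cross-checking the overlap engine on set-valued banks; with real
  rank-valued perturbation profiles the embedding should be replaced by
  the measured ordering.
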