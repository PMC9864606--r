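# screpurpose

Pathway-level connectivity mapping for single-cell drug repurposing.

`screpurpose` implements, as a tested and reusable R pipeline, an
in-silico drug-repurposing analysis for case-versus-control single-cell
RNA-seq cohorts (the motivating setting is multiple sclerosis patients
versus non-inflammatory controls, profiled in CSF and PBMC). Cells pass
standard quality filters and library-size normalization, are annotated to
immune cell types from marker gene sets, and are aggregated per
(cell type, condition) into geometric-mean pseudobulk profiles. Pathway
activation levels computed from these profiles drive the construction of
up/down query signatures, which are scored in *reverse mode* against a
bank of drug perturbation signatures: the best-ranked molecules are those
predicted to push each cell type's disease expression state back toward
the control state. Candidate molecules are then aggregated across cell
types (occurrence counts, exact-membership intersections, common-to-all
sets).

Because patient data cannot ship with a package, a first-class
synthetic-data module generates multi-donor cohorts, pathway databases,
marker sets and drug banks with *planted, recoverable ground truth*, so
every stage of the pipeline is verifiable at desk scale.

## The statistics at the core

For one cell type, let `gm_case(g)` and `gm_control(g)` be the
geometric-mean pseudobulk expression of gene *g* over all case
(respectively control) cells of that type, computed as
`exp(mean log(1 + value))` over cells, where `value = log1p(1e4 * count /
library size)`. The **case-to-normal ratio** is

    CNR(g) = gm_case(g) / gm_control(g)

and the **pathway activation level** of pathway *P* with
activator/repressor roles `ARR(g) ∈ {-1, 0, +1}` is

    PAL(P) = 100 * Σ_{g∈P} ARR(g) · log2 CNR(g) / Σ_{g∈P} |ARR(g)|

PAL is positive for pathways activated in cases, negative for inhibited
ones, and exactly antisymmetric under swapping case and control. The top
10 activated and top 10 inhibited pathways per cell type yield the up and
down query gene lists. Each drug-bank experiment *d* (up set `d.up`, down
set `d.down`) is scored against the query *q* in reverse mode by the
interception (set-overlap) score

    score = (|q.up ∩ d.down| + |q.down ∩ d.up|) / (|q.up| + |q.down|)

with a classic weighted Kolmogorov–Smirnov connectivity score available
as a second, independently verifiable engine.

## Worked example

Generate the default synthetic study (five immune cell types, six case
and six control donors, three pathways up-shifted at log2 fold 2 in
T cells, a drug bank of 5 exact reversers among 200 decoys) and run the
full pipeline:

```r
library(screpurpose)

sc <- default_scenario(seed = 1)
sc$matrix
#> count_matrix: 1000 genes x 5160 cells (2580 case, 2580 control cells)

b <- repurpose_pipeline(sc$matrix, sc$marker_sets, sc$db, sc$bank)
```

QC keeps 5055 of 5160 cells (the generator plants ~2% low-quality cells
with boosted mitochondrial content), and marker-score annotation recovers
the true cell type for 99.96% of them. The three planted pathways
dominate the T-cell PAL table:

```r
head(b$pal[b$pal$cell_type == "TCELL", ], 5)
#>     cell_type pathway         pal n_genes_used
#>         TCELL   PW001   96.550            20
#>         TCELL   PW003   96.095            20
#>         TCELL   PW002   95.382            20
#>         TCELL   PW007    0.086            20
#>         TCELL   PW026   -0.033            20
```

A PAL near +96 means the pathway's genes are, on average, almost one
log2 unit higher in case T cells than in control T cells (the planted
4-fold count shift, compressed by normalization). Reverse-mode ranking
puts all five planted reversers at the top, well clear of the decoys:

```r
head(b$hits$TCELL[, 1:4], 7)
#>   rank experiment    molecule  score
#>   1    EXP003     REV-TCELL-3 0.225
#>   2    EXP005     REV-TCELL-5 0.218
#>   3    EXP002     REV-TCELL-2 0.214
#>   4    EXP004     REV-TCELL-4 0.211
#>   5    EXP001     REV-TCELL-1 0.200
#>   6    EXP028     DECOY-023   0.071
#>   7    EXP037     DECOY-032   0.071

evaluate_recovery(b, sc$truth, top_n = 10)$fraction_recovered
#> [1] 1
```

The bundle also carries the cross-cell-type aggregation: occurrence
counts per molecule (with the "shown if it occurs more than five times"
display flag), the exact-membership intersection partition of the
per-cell-type molecule sets, and the unique/common-to-all summaries.
File-driven runs (`run_pipeline(config, out_dir)`) read a YAML config
naming an MTX matrix directory, a marker file, a pathway GMT and a drug
bank, and write the full report bundle as TSV/JSON.

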