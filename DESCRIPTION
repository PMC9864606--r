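Package: screpurpose
Title: Pathway-Level Connectivity Mapping for Single-Cell Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for in-silico drug repurposing from case
    versus control single-cell RNA-seq data. Cells pass standard quality
    filters and library-size normalization, are annotated to immune cell
    types from marker gene sets, and are aggregated per cell type and
    condition into geometric-mean pseudobulk profiles. Per-pathway
    activation levels (PAL) are computed from activator/repressor-weighted
    log case-to-normal expression ratios; the top activated and inhibited
    pathways yield up/down query signatures that are scored in reverse
    mode against a bank of drug perturbation signatures (set-overlap and
    weighted Kolmogorov-Smirnov engines), with cross-cell-type
    aggregation of candidate molecules. A synthetic-data module generates
    multi-donor cohorts, pathway databases, marker sets, and drug banks
    with planted, recoverable ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
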