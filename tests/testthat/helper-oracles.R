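# Independent oracles and small fixture builders shared across tests.

# Exact two-sided Wilcoxon rank-sum p-value by brute-force enumeration:
# for every assignment of the pooled observations to a group of size n,
# recompute the rank-sum from the raw values and count assignments at
# least as extreme (|W - E[W]|) as the observed one.
oracle_wilcox_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  w_obs <- sum(rank(pooled)[seq_len(n)])
  ew <- n * (N + 1) / 2
  combos <- utils::combn(N, n)
  hits <- 0L
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    xs <- pooled[idx]; ys <- pooled[-idx]
    w <- sum(rank(c(xs, ys))[seq_len(n)])
    if (abs(w - ew) >= abs(w_obs - ew) - 1e-9) hits <- hits + 1L
  }
  hits / ncol(combos)
}

# Exhaustive running-sum KS enrichment score: scan every prefix of the
# ranked list and keep the signed extremum (positive preferred on an
# exact magnitude tie).
oracle_ks_es <- function(s, ranked_list) {
  hit <- ranked_list %in% s
  n_hit <- sum(hit)
  n <- length(ranked_list)
  best <- 0L; running <- 0L
  for (i in seq_len(n)) {
    running <- running + if (hit[i]) n - n_hit else -n_hit
    if (abs(running) > abs(best) ||
        (abs(running) == abs(best) && running > best))
      best <- running
  }
  best / (n_hit * (n - n_hit))
}

# Minimal count matrix: genes x cells from a dense integer matrix with
# default case/control split down the middle.
toy_matrix <- function(counts, condition = NULL, donor = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  n <- ncol(counts)
  if (is.null(condition))
    condition <- rep(c("case", "control"), length.out = n)
  if (is.null(donor)) donor <- rep("d1", n)
  count_matrix(counts,
               data.frame(barcode = colnames(counts), donor = donor,
                          condition = condition, stringsAsFactors = FALSE))
}

# Norm matrix straight from given values (bypasses normalization).
toy_norm <- function(values, condition = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("cell%d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  n <- ncol(values)
  if (is.null(condition))
    condition <- rep(c("case", "control"), length.out = n)
  norm_matrix(values,
              data.frame(barcode = colnames(values), donor = "d1",
                         condition = condition, stringsAsFactors = FALSE))
}

# Uniform annotation: every cell one label.
toy_annotation <- function(barcodes, labels) {
  data.frame(barcode = barcodes, label = labels, margin = 1,
             stringsAsFactors = FALSE)
}

# Expression profile from a named gm vector.
toy_profile <- function(gm, cell_type = "T", condition = "case") {
  expression_profile(cell_type, condition, gm, n_cells = 10)
}

# Hand-built ranked_hits table for aggregation tests.
toy_hits <- function(molecules, cell_type = "T") {
  k <- length(molecules)
  h <- data.frame(rank = seq_len(k),
                  experiment = sprintf("E%03d", seq_len(k)),
                  molecule = molecules, score = rev(seq_len(k)),
                  q_up_d_dn = rep(0, k), q_dn_d_up = rep(0, k),
                  q_up_d_up = rep(0, k), q_dn_d_dn = rep(0, k),
                  stringsAsFactors = FALSE)
  attr(h, "cell_type") <- cell_type
  class(h) <- c("ranked_hits", class(h))
  h
}

# The QC fixture of the cell-filter contract: 6 cells with detected-gene
# counts {50, 200, 2500, 2501, 1000, 1000} and mitochondrial count
# percentages {0, 0, 0, 0, ~15, ~5}.
qc_six_cell_fixture <- function() {
  n_genes <- 2502
  genes <- c("MT-1", sprintf("g%d", seq_len(n_genes - 1)))
  detected <- c(50, 200, 2500, 2501, 1000, 1000)
  m <- Matrix::Matrix(0, nrow = n_genes, ncol = 6, sparse = TRUE)
  rownames(m) <- genes
  colnames(m) <- sprintf("cell%d", 1:6)
  for (j in 1:4) m[1 + seq_len(detected[j]), j] <- 1
  # cells 5 and 6: 999 ordinary genes plus the MT gene
  m[1 + seq_len(999), 5] <- 1; m[1, 5] <- 177   # 177/1176 = 15.05%
  m[1 + seq_len(999), 6] <- 1; m[1, 6] <- 52    # 52/1051 = 4.95%
  toy_matrix(as.matrix(m))
}

# Small on-disk scenario for the file-driven pipeline tests.
write_small_scenario <- function(dir, seed = 101) {
  sc <- default_scenario(seed = seed, n_genes = 300, n_cell_types = 2,
                         cells_per_type_per_donor = 30,
                         n_donors_case = 2, n_donors_control = 2,
                         n_pathways = 10, genes_per_pathway = 10,
                         n_decoys = 30, sig_size = 10,
                         frac_low_quality = 0)
  write_count_matrix(sc$matrix, file.path(dir, "matrix"))
  write_markers(sc$marker_sets, file.path(dir, "markers.tsv"))
  write_gmt(sc$db, file.path(dir, "pathways.gmt"))
  write_drug_bank(sc$bank, file.path(dir, "bank.gmt"))
  write_truth(sc$truth, file.path(dir, "truth.json"))
  cfg <- list(matrix_dir = file.path(dir, "matrix"),
              markers = file.path(dir, "markers.tsv"),
              pathways = file.path(dir, "pathways.gmt"),
              bank = file.path(dir, "bank.gmt"),
              params = list(min_features = 20, max_features = 300,
                            top_n = 20))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  sc
}
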