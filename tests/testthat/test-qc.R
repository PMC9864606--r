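test_that("cell filter applies feature bounds and mito/hb cuts exactly", {
  m <- qc_six_cell_fixture()
  qc <- cell_qc_metrics(m)
  expect_equal(qc$n_detected, c(50, 200, 2500, 2501, 1000, 1000))
  kept <- filter_cells(m)
  expect_identical(colnames(kept$counts), c("cell2", "cell3", "cell6"))

  # boundary semantics: 200 and 2500 inclusive, mito strictly below 10
  expect_true("cell2" %in% colnames(kept$counts))   # exactly min_features
  expect_true("cell3" %in% colnames(kept$counts))   # exactly max_features
  at10 <- toy_matrix(matrix(c(10, 90), nrow = 2,
                            dimnames = list(c("MT-1", "g1"), "c1")))
  expect_equal(ncol(filter_cells(at10, min_features = 1,
                                 max_features = 10)$counts), 0)
  expect_error(filter_cells(m, min_features = 300, max_features = 200),
               "min_features")
})

test_that("hemoglobin content is filtered like mitochondrial content", {
  counts <- matrix(c(15, 85, 5, 95), nrow = 2,
                   dimnames = list(c("HBB", "g1"), c("c1", "c2")))
  m <- toy_matrix(counts)
  kept <- filter_cells(m, min_features = 1, max_features = 10)
  expect_identical(colnames(kept$counts), "c2")
})

test_that("gene filter counts detecting cells", {
  # per-gene detection counts {0, 1, 3, 5} with min_cells = 3 -> 2 survive
  counts <- matrix(0, nrow = 4, ncol = 5)
  counts[2, 1] <- 1
  counts[3, 1:3] <- 1
  counts[4, 1:5] <- 1
  m <- toy_matrix(counts)
  expect_equal(nrow(filter_genes(m, 3)$counts), 2)
  expect_equal(nrow(filter_genes(m, 0)$counts), 4)  # identity
  expect_equal(ncol(filter_genes(m, 3)$counts), 5)  # cell axis unchanged
})

test_that("relaxing any threshold never shrinks the retained set", {
  withr::with_seed(42, {
    for (i in 1:5) {
      counts <- matrix(rpois(80 * 30, lambda = 0.8), nrow = 80)
      rownames(counts) <- c("MT-1", sprintf("g%d", 1:79))
      m <- toy_matrix(counts)
      strict <- filter_cells(m, min_features = 10, max_features = 40,
                             max_mito_pct = 5)
      loose1 <- filter_cells(m, min_features = 5, max_features = 40,
                             max_mito_pct = 5)
      loose2 <- filter_cells(m, min_features = 10, max_features = 60,
                             max_mito_pct = 5)
      loose3 <- filter_cells(m, min_features = 10, max_features = 40,
                             max_mito_pct = 20)
      for (l in list(loose1, loose2, loose3))
        expect_true(all(colnames(strict$counts) %in% colnames(l$counts)))
      g_strict <- filter_genes(m, 5)
      g_loose <- filter_genes(m, 2)
      expect_true(all(rownames(g_strict$counts) %in%
                      rownames(g_loose$counts)))
    }
  })
})

test_that("the pipeline order is cells first, then genes", {
  # a gene detected in exactly 3 cells, one of which fails cell QC:
  # cells-then-genes drops it, genes-then-cells keeps it
  counts <- matrix(0, nrow = 12, ncol = 4)
  counts[1:10, 1:3] <- 1          # three good cells
  counts[1:2, 4] <- 1             # cell4: 3 detected genes, below min 4
  counts[11, c(1, 2, 4)] <- 1     # the sentinel gene
  m <- toy_matrix(counts)
  cells_first <- filter_genes(filter_cells(m, min_features = 4,
                                           max_features = 100), 3)
  genes_first <- filter_cells(filter_genes(m, 3), min_features = 4,
                              max_features = 100)
  expect_false("G11" %in% rownames(cells_first$counts))
  expect_true("G11" %in% rownames(genes_first$counts))
})

test_that("normalization matches its closed form and is scale-invariant", {
  counts <- matrix(c(7, 0), nrow = 2, dimnames = list(c("g1", "g2"), "c1"))
  nm <- normalize_counts(toy_matrix(counts), scale = 1e4)
  expect_equal(nm$values["G1", "c1"], log(1 + 1e4))
  expect_equal(nm$values["G2", "c1"], 0)

  counts2 <- matrix(c(3, 5, 6, 10), nrow = 2)
  m1 <- normalize_counts(toy_matrix(counts2[, 1, drop = FALSE]))
  m2 <- normalize_counts(toy_matrix(counts2[, 2, drop = FALSE]))
  expect_equal(as.numeric(m1$values), as.numeric(m2$values))

  zero_cell <- toy_matrix(matrix(c(1, 0), ncol = 2))
  expect_error(normalize_counts(zero_cell), "zero total")
})

test_that("pseudobulk geometric mean matches closed forms", {
  ann <- toy_annotation(sprintf("cell%d", 1:2), c("T", "T"))
  # identical values v -> gm = 1 + v
  nm <- toy_norm(matrix(c(2.5, 0, 2.5, 0), nrow = 2),
                 condition = c("case", "case"))
  prof <- pseudobulk_geomean(nm, ann, "T", "case")
  expect_equal(unname(prof$gm["G1"]), 3.5)
  expect_equal(unname(prof$gm["G2"]), 1)   # all-zero gene
  expect_equal(prof$n_cells, 2L)

  # values {1, 3} -> gm = exp((ln2 + ln4)/2) = 2*sqrt(2)
  nm2 <- toy_norm(matrix(c(1, 3), nrow = 1),
                  condition = c("case", "case"))
  expect_equal(unname(pseudobulk_geomean(nm2, ann, "T", "case")$gm["G1"]),
               2 * sqrt(2))

  expect_error(pseudobulk_geomean(nm2, ann, "T", "control"),
               "control")
})

test_that("pseudobulk is invariant to cell order", {
  withr::with_seed(7, {
    v <- matrix(runif(60, 0, 4), nrow = 6)
    nm <- toy_norm(v, condition = rep("case", 10))
    ann <- toy_annotation(colnames(nm$values), rep("T", 10))
    p1 <- pseudobulk_geomean(nm, ann, "T", "case")
    perm <- sample(10)
    nm2 <- norm_matrix(nm$values[, perm], nm$cell_meta[perm, ])
    p2 <- pseudobulk_geomean(nm2, ann, "T", "case")
    expect_equal(p1$gm, p2$gm)
  })
})
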