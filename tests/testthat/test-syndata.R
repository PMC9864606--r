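test_that("pathway generation honors sizes, overlap and determinism", {
  # forced by sizes: one pathway over a 5-gene universe contains all 5
  db1 <- generate_pathway_db(1, 5, c("a", "b", "c", "d", "e"), seed = 3)
  expect_setequal(db1$pathways[[1]]$genes, toupper(c("a", "b", "c", "d", "e")))

  # same seed -> byte-identical GMT serialization
  uni <- sprintf("G%04d", 1:1000)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(generate_pathway_db(10, 20, uni, seed = 7), f1)
  write_gmt(generate_pathway_db(10, 20, uni, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))

  # zero overlap with a large universe: pairwise disjoint, 800 genes used
  db <- generate_pathway_db(40, 20, uni, overlap_fraction = 0, seed = 1)
  genes <- unlist(lapply(db$pathways, function(p) p$genes))
  expect_length(genes, 800)
  expect_equal(length(unique(genes)), 800)

  # adjacent overlap close to requested fraction
  db_ov <- generate_pathway_db(10, 20, uni, overlap_fraction = 0.5, seed = 1)
  shared <- vapply(2:10, function(i)
    length(intersect(db_ov$pathways[[i]]$genes,
                     db_ov$pathways[[i - 1]]$genes)), integer(1))
  expect_true(all(shared == 10))

  expect_error(generate_pathway_db(1, 6, c("a", "b"), seed = 1), "universe")
})

test_that("cohort counts are deterministic and carry labels", {
  cfg <- syn_config(n_genes = 120, n_cell_types = 2,
                    cells_per_type_per_donor = 5, n_donors_case = 2,
                    n_donors_control = 2, seed = 11)
  uni <- syn_gene_universe(cfg)
  db <- generate_pathway_db(4, 10, uni$filler, seed = 11)
  c1 <- generate_cohort(cfg, db)
  c2 <- generate_cohort(cfg, db)
  expect_identical(as.matrix(c1$matrix$counts), as.matrix(c2$matrix$counts))
  expect_setequal(unique(c1$matrix$cell_meta$condition), c("case", "control"))
  expect_equal(ncol(c1$matrix$counts), 2 * 5 * 4)
  expect_setequal(unique(c1$truth$cell_type_of_cell), c("TCELL", "BCELL"))
})

test_that("planted fold change shifts case means by ~2^log2_fold", {
  cfg <- syn_config(n_genes = 200, n_cell_types = 2,
                    cells_per_type_per_donor = 250, n_donors_case = 2,
                    n_donors_control = 2, frac_low_quality = 0,
                    seed = 5)
  uni <- syn_gene_universe(cfg)
  db <- generate_pathway_db(4, 10, uni$filler, seed = 5)
  cfg <- syn_config(n_genes = 200, n_cell_types = 2,
                    cells_per_type_per_donor = 250, n_donors_case = 2,
                    n_donors_control = 2, frac_low_quality = 0, seed = 5,
                    planted = list(planted_effect("PW001", "TCELL", 2)))
  ch <- generate_cohort(cfg, db)
  m <- ch$matrix
  is_t <- ch$truth$cell_type_of_cell[colnames(m$counts)] == "TCELL"
  pg <- db$pathways$PW001$genes
  case_mean <- mean(as.matrix(m$counts)[pg, is_t & m$cell_meta$condition == "case"])
  ctrl_mean <- mean(as.matrix(m$counts)[pg, is_t & m$cell_meta$condition == "control"])
  expect_gt(case_mean / ctrl_mean, 3.5)
  expect_lt(case_mean / ctrl_mean, 4.5)
  # untargeted cell type unaffected
  case_b <- mean(as.matrix(m$counts)[pg, !is_t & m$cell_meta$condition == "case"])
  ctrl_b <- mean(as.matrix(m$counts)[pg, !is_t & m$cell_meta$condition == "control"])
  expect_lt(abs(log2(case_b / ctrl_b)), 0.3)
})

test_that("unplanted cohorts have null case/control differences", {
  cfg <- syn_config(n_genes = 200, n_cell_types = 1,
                    cells_per_type_per_donor = 100, n_donors_case = 1,
                    n_donors_control = 1, frac_low_quality = 0, seed = 9)
  uni <- syn_gene_universe(cfg)
  db <- generate_pathway_db(2, 10, uni$filler, seed = 9)
  ch <- generate_cohort(cfg, db)
  cnts <- as.matrix(ch$matrix$counts)
  is_case <- ch$matrix$cell_meta$condition == "case"
  p <- apply(cnts, 1, function(g)
    stats::t.test(g[is_case], g[!is_case])$p.value)
  expect_lt(mean(p < 0.01, na.rm = TRUE), 0.05)
})

test_that("cohort generation validates marker sets and planted references", {
  cfg <- syn_config(n_genes = 120, n_cell_types = 2,
                    cells_per_type_per_donor = 3, seed = 1)
  uni <- syn_gene_universe(cfg)
  db <- generate_pathway_db(2, 5, uni$filler, seed = 1)
  bad_markers <- list(TCELL = c("X1", "X2"), BCELL = c("X2", "X3"))
  expect_error(generate_cohort(cfg, db, bad_markers), "disjoint")
  cfg_bad <- syn_config(n_genes = 120, n_cell_types = 2,
                        cells_per_type_per_donor = 3, seed = 1,
                        planted = list(planted_effect("NOPE", "TCELL", 1)))
  expect_error(generate_cohort(cfg_bad, db), "NOPE")
  expect_error(planted_effect("PW001", "TCELL", 0), "nonzero")
})

test_that("drug bank plants exact reversers and honest decoys", {
  cfg <- syn_config(n_genes = 300, n_cell_types = 2,
                    cells_per_type_per_donor = 3, seed = 2,
                    planted = list(planted_effect("PW001", "TCELL", 2)))
  uni <- syn_gene_universe(cfg)
  db <- generate_pathway_db(4, 20, uni$filler, seed = 2)
  ch <- generate_cohort(cfg, db)
  truth <- plant_reversers(ch$truth, n_reversers = 1)

  # no decoys, one reverser: a single experiment with DN inside the
  # planted up-pathway genes
  bank0 <- generate_drug_bank(db, truth, n_decoys = 0, sig_size = 10,
                              gene_universe = uni$all, seed = 2)
  expect_length(bank0, 1)
  expect_true(all(bank0$experiments[[1]]$down %in% db$pathways$PW001$genes))

  # decoy sets never touch planted pathway genes
  bank <- generate_drug_bank(db, truth, n_decoys = 30, sig_size = 10,
                             gene_universe = uni$all, seed = 2)
  planted_genes <- db$pathways$PW001$genes
  for (e in bank$experiments[-1])
    expect_length(intersect(c(e$up, e$down), planted_genes), 0)

  # empty UP side (no down-planted pathways) is padded; fraction recorded
  expect_length(bank0$experiments[[1]]$up, 10)
  expect_equal(bank$metadata$pad_fraction[[truth$planted_reversers$drug[1]]],
               0.5)

  # determinism
  bank2 <- generate_drug_bank(db, truth, n_decoys = 30, sig_size = 10,
                              gene_universe = uni$all, seed = 2)
  expect_identical(bank$experiments, bank2$experiments)
})

test_that("molecule-level dedup separates experiments from molecules", {
  exps <- lapply(1:3, function(i)
    list(exp_id = sprintf("E%d", i), molecule = "drugA",
         cell_line = "L", dose = sprintf("%dnM", i),
         up = c("A", "B"), down = c("C", "D")))
  bank <- drug_bank(exps)
  mols <- unique(vapply(bank$experiments, function(e) e$molecule,
                        character(1)))
  expect_length(bank, 3)
  expect_length(mols, 1)
})
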