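test_that("occurrence counting follows the experiment-level rule", {
  hits <- list(T = toy_hits(c("m1", "m1", "m2")),
               B = toy_hits(c("m1", "m3")),
               NK = toy_hits(c("m1", "m2", "m3")))
  occ <- occurrence_counts(hits, display_min = 3)
  expect_equal(occ$count[occ$molecule == "m1"], 4)  # two in one type count twice
  expect_equal(occ$count[occ$molecule == "m2"], 2)
  expect_equal(occ$count[occ$molecule == "m3"], 2)
  expect_equal(sum(occ$count), sum(vapply(hits, nrow, integer(1))))
  expect_equal(occ$molecule[occ$shown], "m1")

  # molecule-level mode counts each molecule once per cell type
  occ_m <- occurrence_counts(hits, display_min = 3, level = "molecule")
  expect_equal(occ_m$count[occ_m$molecule == "m1"], 3)

  one <- occurrence_counts(list(T = toy_hits(c("m", "m"))))
  expect_equal(one$count, 2)
})

test_that("cell-type intersections form an exact-membership partition", {
  # {A,B}, {B,C}, {B} -> {all three}:{B}, {1}:{A}, {2}:{C}
  hits <- list(ct1 = toy_hits(c("A", "B")), ct2 = toy_hits(c("B", "C")),
               ct3 = toy_hits("B"))
  tab <- intersect_celltypes(hits)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$molecules[tab$cell_types == "ct1,ct2,ct3"], "B")
  expect_equal(tab$molecules[tab$cell_types == "ct1"], "A")
  expect_equal(tab$molecules[tab$cell_types == "ct2"], "C")
  expect_equal(tab$size, c(1, 1, 1))

  # identical sets: one group labeled with both types
  same <- list(x = toy_hits(c("A", "B")), y = toy_hits(c("A", "B")))
  tab2 <- intersect_celltypes(same)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$cell_types, "x,y")
  expect_equal(tab2$size, 2)

  # disjoint sets: two singleton-subset groups
  disj <- list(x = toy_hits("A"), y = toy_hits("B"))
  expect_equal(sort(intersect_celltypes(disj)$cell_types), c("x", "y"))
})

test_that("unique and common molecule sets follow set arithmetic", {
  hits <- list(a = toy_hits(c("A", "B", "C")), b = toy_hits(c("B", "C")),
               c = toy_hits(c("B", "C", "D")))
  uc <- unique_and_common(hits)
  expect_equal(uc$unique_count, 4)
  expect_equal(uc$common, c("B", "C"))

  single <- unique_and_common(list(a = toy_hits(c("X", "Y"))))
  expect_equal(single$unique_count, 2)
  expect_equal(single$common, c("X", "Y"))

  with_empty <- list(a = toy_hits(c("A")), b = toy_hits(character(0)))
  expect_equal(unique_and_common(with_empty)$common, character(0))
})

test_that("aggregation conserves counts and partitions the union", {
  withr::with_seed(83, {
    mols <- sprintf("M%02d", 1:30)
    for (i in 1:50) {
      n_types <- sample(2:6, 1)
      hits <- stats::setNames(lapply(seq_len(n_types), function(j)
        toy_hits(sample(mols, sample(1:15, 1), replace = TRUE))),
        sprintf("ct%d", seq_len(n_types)))
      occ <- occurrence_counts(hits)
      expect_equal(sum(occ$count), sum(vapply(hits, nrow, integer(1))))
      tab <- intersect_celltypes(hits)
      uc <- unique_and_common(hits)
      expect_equal(sum(tab$size), uc$unique_count)
      expect_setequal(unlist(strsplit(tab$molecules, ";")),
                      unique(unlist(lapply(hits, function(h) h$molecule))))
    }
  })
})

test_that("recovery evaluation reports ranks and validates references", {
  bundle <- list(hits = list(T = toy_hits(c("REV-1", "d1", "d2"))),
                 bank_molecules = c("REV-1", "REV-2", "d1", "d2"))
  truth <- syn_truth(planted_reversers = data.frame(
    drug = c("REV-1", "REV-2"), cell_type = "T", stringsAsFactors = FALSE))
  rec <- evaluate_recovery(bundle, truth, top_n = 2)
  expect_equal(rec$per_reverser$best_rank, c(1L, NA_integer_))
  expect_equal(rec$per_reverser$in_top_n, c(TRUE, FALSE))
  expect_equal(rec$fraction_recovered, 0.5)
  # rank 1 is in-top for any window
  expect_true(evaluate_recovery(bundle, syn_truth(
    planted_reversers = data.frame(drug = "REV-1", cell_type = "T")),
    top_n = 1)$per_reverser$in_top_n)

  truth_bad <- syn_truth(planted_reversers = data.frame(
    drug = "ghost", cell_type = "T", stringsAsFactors = FALSE))
  expect_error(evaluate_recovery(bundle, truth_bad), "not in the bank")
  truth_ct <- syn_truth(planted_reversers = data.frame(
    drug = "d1", cell_type = "missing", stringsAsFactors = FALSE))
  expect_error(evaluate_recovery(bundle, truth_ct), "cell type")
})

test_that("the file-driven pipeline runs, validates config and is reproducible", {
  dir <- withr::local_tempdir()
  sc <- write_small_scenario(dir)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  b <- run_pipeline(file.path(dir, "config.yaml"), out1)
  expect_true(all(c("TCELL", "BCELL") %in% names(b$hits)))
  expect_true(file.exists(file.path(out1, "hits_TCELL.tsv")))
  expect_true(file.exists(file.path(out1, "pal.tsv")))

  # recovery of the planted reversers from the written bundle
  rec <- evaluate_recovery(b, sc$truth, top_n = 10)
  expect_equal(rec$fraction_recovered, 1)

  # rerun: byte-identical TSV outputs
  run_pipeline(file.path(dir, "config.yaml"), out2)
  for (f in list.files(out1, pattern = "\\.tsv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     info = f)
  }

  # config without the bank names the rank stage
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$bank <- NULL
  expect_error(run_pipeline(cfg, file.path(dir, "out3")), "rank stage")
})

test_that("a one-cell-type cohort yields exactly one hits table", {
  sc <- default_scenario(seed = 7, n_genes = 200, n_cell_types = 1,
                         cells_per_type_per_donor = 25,
                         n_donors_case = 2, n_donors_control = 2,
                         n_pathways = 8, genes_per_pathway = 10,
                         n_decoys = 20, sig_size = 10,
                         frac_low_quality = 0)
  b <- repurpose_pipeline(sc$matrix, sc$marker_sets, sc$db, sc$bank,
                          params = list(min_features = 10,
                                        max_features = 200))
  expect_length(b$hits, 1)
  expect_named(b$hits, "TCELL")
})
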