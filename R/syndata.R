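#' Configuration for the synthetic scRNA-seq cohort generator
#'
#' Defines a multi-donor case/control cohort with marker-structured immune
#' cell types and optional condition-specific expression shifts planted in
#' chosen pathways of chosen cell types. Defaults emulate a CSF-style
#' cohort: six case and six control donors, five immune cell types, and
#' enough cells per (type, condition) side (> 500) for pathway-level
#' signal recovery.
#'
#' Counts are negative binomial with a single global dispersion
#' (variance = mu + dispersion * mu^2). Markers are implemented as a
#' mean-fold elevation (not exclusive expression), so marker-score
#' annotation is a nontrivial but solvable task. A small fraction of
#' "low-quality" cells get boosted mitochondrial counts so the QC filters
#' have real work to do; mitochondrial and hemoglobin genes are named with
#' the conventional "MT-" and "HB" prefixes.
#'
#' @param n_genes total genes in the universe (markers + MT + HB + filler).
#' @param n_cell_types number of immune cell types (max 10).
#' @param cells_per_type_per_donor cells of each type contributed by each
#'   donor.
#' @param n_donors_case,n_donors_control donors per condition.
#' @param nb_mean baseline negative-binomial mean per gene per cell.
#' @param nb_dispersion global NB dispersion (> 0).
#' @param marker_fold mean multiplier for a type's marker genes in cells of
#'   that type (> 1).
#' @param markers_per_type marker genes per cell type.
#' @param n_mito_genes,n_hb_genes genes named with "MT-" / "HB" prefixes.
#' @param frac_low_quality fraction of cells with boosted mitochondrial
#'   content (removed by default QC).
#' @param mito_boost mean multiplier for MT genes in low-quality cells.
#' @param planted list of [planted_effect()] entries.
#' @param seed integer seed; every generated object is a pure function of
#'   the configuration including this seed.
#' @return An object of class `syn_config`.
#' @export
syn_config <- function(n_genes = 1000,
                       n_cell_types = 5,
                       cells_per_type_per_donor = 86,
                       n_donors_case = 6,
                       n_donors_control = 6,
                       nb_mean = 0.5,
                       nb_dispersion = 0.3,
                       marker_fold = 8,
                       markers_per_type = 10,
                       n_mito_genes = 5,
                       n_hb_genes = 3,
                       frac_low_quality = 0.02,
                       mito_boost = 40,
                       planted = list(),
                       seed = 1L) {
  stopifnot(n_genes > 0, n_cell_types > 0, cells_per_type_per_donor > 0,
            n_donors_case > 0, n_donors_control > 0,
            nb_mean > 0, nb_dispersion > 0, marker_fold > 1,
            markers_per_type > 0, frac_low_quality >= 0,
            frac_low_quality < 1, mito_boost >= 1)
  if (n_cell_types > length(immune_type_pool()))
    stop("at most ", length(immune_type_pool()), " cell types supported")
  reserved <- n_cell_types * markers_per_type + n_mito_genes + n_hb_genes
  if (reserved >= n_genes)
    stop("n_genes too small for the requested marker/MT/HB genes")
  for (p in planted) {
    if (!inherits(p, "planted_effect")) stop("planted entries must be planted_effect objects")
  }
  structure(list(n_genes = n_genes, n_cell_types = n_cell_types,
                 cells_per_type_per_donor = cells_per_type_per_donor,
                 n_donors_case = n_donors_case,
                 n_donors_control = n_donors_control,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 marker_fold = marker_fold,
                 markers_per_type = markers_per_type,
                 n_mito_genes = n_mito_genes, n_hb_genes = n_hb_genes,
                 frac_low_quality = frac_low_quality,
                 mito_boost = mito_boost,
                 planted = planted, seed = as.integer(seed)),
            class = "syn_config")
}

#' A condition-specific expression shift planted in one pathway of one
#' cell type
#'
#' In case-condition cells of `cell_type`, the mean of every gene of
#' `pathway_id` is multiplied by `2^log2_fold` (sign gives direction).
#'
#' @param pathway_id pathway identifier (must exist in the pathway
#'   database passed to [generate_cohort()]).
#' @param cell_type targeted cell-type label.
#' @param log2_fold nonzero log2 fold change.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(pathway_id, cell_type, log2_fold) {
  if (log2_fold == 0) stop("log2_fold must be nonzero")
  structure(list(pathway_id = pathway_id, cell_type = cell_type,
                 log2_fold = log2_fold),
            class = "planted_effect")
}

immune_type_pool <- function() {
  c("TCELL", "BCELL", "NK", "MONO", "MDC",
    "GRANULO", "PLASMA", "PDC", "MEGAK", "ERYTH")
}

#' Cell-type labels implied by a configuration
#' @param config a [syn_config()].
#' @return character vector of cell-type labels.
#' @export
syn_cell_types <- function(config) {
  immune_type_pool()[seq_len(config$n_cell_types)]
}

#' Gene universe implied by a configuration
#'
#' Genes are partitioned into per-type marker blocks, mitochondrial
#' ("MT-") and hemoglobin ("HB") genes, and filler genes. Pathways are by
#' default sampled from the filler block so that marker structure and
#' pathway structure stay orthogonal.
#'
#' @param config a [syn_config()].
#' @return list with components `all`, `markers` (named list per type),
#'   `mito`, `hb`, `filler`.
#' @export
syn_gene_universe <- function(config) {
  types <- syn_cell_types(config)
  markers <- lapply(types, function(t)
    sprintf("%s-MK%02d", t, seq_len(config$markers_per_type)))
  names(markers) <- types
  mito <- if (config$n_mito_genes > 0)
    sprintf("MT-G%d", seq_len(config$n_mito_genes)) else character(0)
  hb <- if (config$n_hb_genes > 0)
    sprintf("HB%s%d", rep_len(c("B", "A", "G"), config$n_hb_genes),
            seq_len(config$n_hb_genes)) else character(0)
  n_fill <- config$n_genes - length(unlist(markers)) - length(mito) - length(hb)
  filler <- sprintf("G%04d", seq_len(n_fill))
  list(all = c(unlist(markers, use.names = FALSE), mito, hb, filler),
       markers = markers, mito = mito, hb = hb, filler = filler)
}

#' Generate a synthetic pathway database
#'
#' Samples `n_pathways` gene sets of `genes_per_pathway` genes from a gene
#' universe. Adjacent pathways (i, i+1) share approximately
#' `overlap_fraction` of their genes; with `overlap_fraction = 0` and a
#' large enough universe all sets are pairwise disjoint. Every gene
#' carries an activator/repressor weight in \{-1, +1\}; by default all +1,
#' with a configurable fraction flipped to repressors.
#'
#' @param n_pathways number of gene sets.
#' @param genes_per_pathway set size (<= length of the universe).
#' @param gene_universe character vector of candidate gene IDs.
#' @param overlap_fraction fraction in [0, 1) of genes shared between
#'   adjacent pathways.
#' @param seed integer seed (generation is a pure function of it).
#' @param frac_repressor fraction of genes per pathway assigned ARR -1.
#' @return A [pathway_db()] with IDs "PW001", "PW002", ...
#' @export
generate_pathway_db <- function(n_pathways, genes_per_pathway, gene_universe,
                                overlap_fraction = 0, seed = 1L,
                                frac_repressor = 0) {
  stopifnot(n_pathways > 0, genes_per_pathway > 0,
            overlap_fraction >= 0, overlap_fraction < 1)
  gene_universe <- toupper(gene_universe)
  if (genes_per_pathway > length(gene_universe))
    stop("genes_per_pathway exceeds the gene universe size")
  withr::with_seed(as.integer(seed), {
    unused <- gene_universe
    prev <- character(0)
    paths <- vector("list", n_pathways)
    for (i in seq_len(n_pathways)) {
      n_share <- min(round(overlap_fraction * genes_per_pathway), length(prev))
      shared <- if (n_share > 0) sample(prev, n_share) else character(0)
      n_new <- genes_per_pathway - n_share
      pool <- setdiff(unused, shared)
      if (length(pool) >= n_new) {
        fresh <- sample(pool, n_new)
      } else {
        extra <- setdiff(gene_universe, c(shared, pool))
        fresh <- c(pool, sample(extra, n_new - length(pool)))
      }
      genes <- c(shared, fresh)
      arr <- stats::setNames(rep(1, genes_per_pathway), genes)
      if (frac_repressor > 0) {
        n_rep <- round(frac_repressor * genes_per_pathway)
        if (n_rep > 0) arr[sample(genes, n_rep)] <- -1
      }
      paths[[i]] <- list(genes = genes, arr = arr, category = "simulated",
                         description = "simulated")
      unused <- setdiff(unused, genes)
      prev <- genes
    }
    names(paths) <- sprintf("PW%03d", seq_len(n_pathways))
    pathway_db(paths)
  })
}

#' Ground-truth record for a synthetic scenario
#'
#' @param planted_effects list of [planted_effect()] entries.
#' @param planted_reversers data.frame with columns `drug`, `cell_type`
#'   (drugs constructed to reverse the planted shifts of that type).
#' @param cell_type_of_cell named character vector, cell ID -> true label.
#' @param low_quality character vector of cell IDs generated as
#'   low-quality (boosted mitochondrial content).
#' @return An object of class `syn_truth`.
#' @export
syn_truth <- function(planted_effects = list(),
                      planted_reversers = data.frame(drug = character(0),
                                                     cell_type = character(0)),
                      cell_type_of_cell = character(0),
                      low_quality = character(0)) {
  structure(list(planted_effects = planted_effects,
                 planted_reversers = planted_reversers,
                 cell_type_of_cell = cell_type_of_cell,
                 low_quality = low_quality),
            class = "syn_truth")
}

#' Generate a synthetic multi-donor case/control cohort
#'
#' Draws per-gene, per-cell counts from a negative binomial with mean
#' `nb_mean` and global dispersion `nb_dispersion`. For a cell of type t,
#' genes in `marker_sets[[t]]` have their mean multiplied by
#' `marker_fold`; for case-condition cells of type t, genes of each
#' planted pathway targeting t have their mean multiplied by
#' `2^log2_fold`. Low-quality cells get their mitochondrial gene means
#' multiplied by `mito_boost`. Donor and condition labels are attached to
#' every cell; the whole draw is a pure function of `config$seed`.
#'
#' @param config a [syn_config()].
#' @param db a [pathway_db()] containing every planted pathway.
#' @param marker_sets named list (cell type -> marker genes), pairwise
#'   disjoint; defaults to the marker blocks of [syn_gene_universe()].
#' @return list with elements `matrix` (a [count_matrix()]) and `truth`
#'   (a [syn_truth()]).
#' @export
generate_cohort <- function(config, db, marker_sets = NULL) {
  uni <- syn_gene_universe(config)
  if (is.null(marker_sets)) marker_sets <- uni$markers
  marker_sets <- lapply(marker_sets, toupper)
  all_mk <- unlist(marker_sets, use.names = FALSE)
  if (anyDuplicated(all_mk)) stop("marker sets must be pairwise disjoint")
  types <- syn_cell_types(config)
  if (!all(names(marker_sets) %in% types))
    stop("marker sets name unknown cell types")
  for (p in config$planted) {
    if (!p$pathway_id %in% names(db$pathways))
      stop("planted pathway not in database: ", p$pathway_id)
    if (!p$cell_type %in% types)
      stop("planted cell type unknown: ", p$cell_type)
  }
  genes <- uni$all
  g_idx <- stats::setNames(seq_along(genes), genes)
  nb_size <- 1 / config$nb_dispersion

  donors <- c(sprintf("caseD%d", seq_len(config$n_donors_case)),
              sprintf("ctrlD%d", seq_len(config$n_donors_control)))
  conds <- c(rep("case", config$n_donors_case),
             rep("control", config$n_donors_control))
  n_per <- config$cells_per_type_per_donor
  n_cells <- length(donors) * length(types) * n_per

  # per-(type, condition) mean vectors
  mu_of <- function(type, cond) {
    mu <- rep(config$nb_mean, length(genes))
    mu[g_idx[marker_sets[[type]]]] <- mu[g_idx[marker_sets[[type]]]] *
      config$marker_fold
    if (cond == "case") {
      for (p in config$planted) {
        if (p$cell_type == type) {
          pg <- intersect(db$pathways[[p$pathway_id]]$genes, genes)
          mu[g_idx[pg]] <- mu[g_idx[pg]] * 2^p$log2_fold
        }
      }
    }
    mu
  }

  withr::with_seed(config$seed, {
    big <- matrix(0L, nrow = length(genes), ncol = n_cells)
    meta <- vector("list", length(donors) * length(types))
    truth_type <- character(n_cells)
    lowq <- character(0)
    all_ids <- sprintf("C%06d", seq_len(n_cells))
    cell_i <- 0L
    b <- 0L
    for (d in seq_along(donors)) {
      for (t in types) {
        b <- b + 1L
        mu <- mu_of(t, conds[d])
        cols <- cell_i + seq_len(n_per)
        big[, cols] <- stats::rnbinom(length(genes) * n_per,
                                      size = nb_size, mu = mu)
        # redraw MT rows for low-quality cells with boosted means
        is_lq <- stats::runif(n_per) < config$frac_low_quality
        if (any(is_lq) && length(uni$mito)) {
          mt <- g_idx[uni$mito]
          big[mt, cols[is_lq]] <- stats::rnbinom(length(mt) * sum(is_lq),
                                                 size = nb_size,
                                                 mu = mu[mt] * config$mito_boost)
        }
        meta[[b]] <- data.frame(barcode = all_ids[cols], donor = donors[d],
                                condition = conds[d],
                                stringsAsFactors = FALSE)
        truth_type[cols] <- t
        lowq <- c(lowq, all_ids[cols[is_lq]])
        cell_i <- cell_i + n_per
      }
    }
    rownames(big) <- genes; colnames(big) <- all_ids
    counts <- Matrix::Matrix(big, sparse = TRUE)
    cell_meta <- do.call(rbind, meta)
    m <- count_matrix(counts, cell_meta)
    names(truth_type) <- colnames(counts)
    list(matrix = m,
         truth = syn_truth(planted_effects = config$planted,
                           cell_type_of_cell = truth_type,
                           low_quality = lowq))
  })
}

#' Declare which drugs of the synthetic bank reverse the planted shifts
#'
#' Adds `n_reversers` drug names per cell type that carries at least one
#' planted effect; [generate_drug_bank()] then builds one exact-reversal
#' experiment per declared reverser.
#'
#' @param truth a [syn_truth()] with planted effects.
#' @param n_reversers reverser drugs per targeted cell type.
#' @return the updated `syn_truth`.
#' @export
plant_reversers <- function(truth, n_reversers = 5) {
  targeted <- unique(vapply(truth$planted_effects,
                            function(p) p$cell_type, character(1)))
  if (!length(targeted)) stop("no planted effects to reverse")
  rev <- do.call(rbind, lapply(targeted, function(t)
    data.frame(drug = sprintf("REV-%s-%d", t, seq_len(n_reversers)),
               cell_type = t, stringsAsFactors = FALSE)))
  truth$planted_reversers <- rev
  truth
}

#' Generate a synthetic drug-signature bank with planted reversers
#'
#' For each planted reverser declared in `truth`, emits an experiment
#' whose DOWN set is drawn from the up-planted pathway genes of its
#' targeted cell type and whose UP set from the down-planted pathway genes
#' (an empty side is padded with random non-planted genes; the pad
#' fraction is recorded in the bank metadata). Decoy experiments sample
#' their UP/DOWN sets uniformly from non-planted genes, so with a large
#' enough non-planted pool decoys are disjoint from every planted pathway.
#' A `corrupt_fraction > 0` replaces that fraction of each reverser's
#' signature genes with random non-planted genes, producing harder partial
#' positives.
#'
#' @param db the [pathway_db()] the effects were planted in.
#' @param truth a [syn_truth()] with `planted_reversers` set (see
#'   [plant_reversers()]).
#' @param n_decoys number of decoy experiments.
#' @param sig_size genes per signature side.
#' @param gene_universe character vector to draw decoy/pad genes from.
#' @param seed integer seed.
#' @param corrupt_fraction fraction in [0, 1] of each reverser side
#'   replaced by random non-planted genes (default 0 = exact reversal).
#' @return A [drug_bank()]. Decoy molecules are named "DECOY-001", ...;
#'   each experiment carries dose and cell-line tags.
#' @export
generate_drug_bank <- function(db, truth, n_decoys = 200, sig_size = 50,
                               gene_universe, seed = 1L,
                               corrupt_fraction = 0) {
  gene_universe <- toupper(gene_universe)
  if (sig_size > length(gene_universe))
    stop("sig_size exceeds the gene universe size")
  planted_genes <- unique(unlist(lapply(truth$planted_effects, function(p)
    db$pathways[[p$pathway_id]]$genes)))
  pool <- setdiff(gene_universe, planted_genes)
  pad_frac <- c()
  withr::with_seed(as.integer(seed), {
    exps <- list()
    rv <- truth$planted_reversers
    for (i in seq_len(nrow(rv))) {
      t <- rv$cell_type[i]
      up_planted <- unique(unlist(lapply(truth$planted_effects, function(p)
        if (p$cell_type == t && p$log2_fold > 0)
          db$pathways[[p$pathway_id]]$genes else NULL)))
      dn_planted <- unique(unlist(lapply(truth$planted_effects, function(p)
        if (p$cell_type == t && p$log2_fold < 0)
          db$pathways[[p$pathway_id]]$genes else NULL)))
      draw_side <- function(src, avoid) {
        n_src <- min(sig_size, length(src))
        side <- if (n_src > 0) sample(src, n_src) else character(0)
        if (corrupt_fraction > 0 && length(side)) {
          n_cor <- round(corrupt_fraction * length(side))
          if (n_cor > 0) {
            repl <- sample(setdiff(pool, avoid), n_cor)
            side[seq_len(n_cor)] <- repl
          }
        }
        n_pad <- sig_size - length(side)
        if (n_pad > 0)
          side <- c(side, sample(setdiff(pool, c(side, avoid)), n_pad))
        side
      }
      dn <- draw_side(up_planted, character(0))
      up <- draw_side(dn_planted, dn)
      pad_frac[rv$drug[i]] <-
        1 - (min(sig_size, length(up_planted)) +
             min(sig_size, length(dn_planted))) / (2 * sig_size)
      exps[[length(exps) + 1L]] <-
        list(exp_id = sprintf("EXP%03d", length(exps) + 1L),
             molecule = rv$drug[i], cell_line = "SYN1", dose = "10uM",
             up = up, down = dn)
    }
    for (j in seq_len(n_decoys)) {
      g <- sample(pool, 2 * sig_size)
      exps[[length(exps) + 1L]] <-
        list(exp_id = sprintf("EXP%03d", length(exps) + 1L),
             molecule = sprintf("DECOY-%03d", j),
             cell_line = "SYN1", dose = "10uM",
             up = g[seq_len(sig_size)], down = g[sig_size + seq_len(sig_size)])
    }
    drug_bank(exps, gene_universe = gene_universe,
              metadata = list(pad_fraction = as.list(pad_frac)))
  })
}

#' Build the default synthetic study scenario
#'
#' One call that wires the generators together under a single seed: the
#' default cohort configuration with three pathways up-shifted at
#' `log2_fold = 2` in the first cell type, a 40-pathway database of
#' 20-gene sets over the filler genes, and a drug bank of five exact
#' reversers among 200 decoys (signature size 50).
#'
#' @param seed integer master seed.
#' @param log2_fold planted effect size.
#' @param n_planted number of planted pathways (all in the first type).
#' @param n_pathways,genes_per_pathway pathway database shape.
#' @param n_reversers,n_decoys,sig_size drug-bank shape.
#' @param ... further overrides passed to [syn_config()].
#' @return list with `config`, `db`, `marker_sets`, `matrix`, `truth`,
#'   `bank`.
#' @export
default_scenario <- function(seed = 1L, log2_fold = 2, n_planted = 3,
                             n_pathways = 40, genes_per_pathway = 20,
                             n_reversers = 5, n_decoys = 200, sig_size = 50,
                             ...) {
  seed <- as.integer(seed)
  cfg0 <- syn_config(seed = seed, ...)
  uni <- syn_gene_universe(cfg0)
  db <- generate_pathway_db(n_pathways, genes_per_pathway, uni$filler,
                            overlap_fraction = 0, seed = seed)
  target <- syn_cell_types(cfg0)[1]
  planted <- lapply(names(db$pathways)[seq_len(n_planted)], function(id)
    planted_effect(id, target, log2_fold))
  cfg <- syn_config(seed = seed, planted = planted, ...)
  cohort <- generate_cohort(cfg, db)
  truth <- plant_reversers(cohort$truth, n_reversers = n_reversers)
  bank <- generate_drug_bank(db, truth, n_decoys = n_decoys,
                             sig_size = sig_size, gene_universe = uni$all,
                             seed = seed)
  list(config = cfg, db = db, marker_sets = uni$markers,
       matrix = cohort$matrix, truth = truth, bank = bank)
}
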