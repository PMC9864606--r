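#' Occurrence counts of molecules across cell-type hit lists
#'
#' Counts every hit row per molecule across all cell types. The default
#' is experiment-level counting (a molecule hit by two experiments within
#' one cell type counts twice); `level = "molecule"` counts each molecule
#' at most once per cell type. The full table is always returned; the
#' `shown` column marks rows at or above the display threshold (the
#' "occurs more than five times" display rule, i.e. count >= 6 by
#' default).
#'
#' @param hits named list, cell type -> `ranked_hits`.
#' @param display_min display threshold on the count.
#' @param level `"experiment"` (default) or `"molecule"`.
#' @return data.frame with columns `molecule`, `count`, `shown`, sorted
#'   by descending count then molecule name.
#' @export
occurrence_counts <- function(hits, display_min = 6,
                              level = c("experiment", "molecule")) {
  level <- match.arg(level)
  if (!length(hits)) stop("at least one cell type required")
  mols <- unlist(lapply(hits, function(h) {
    if (level == "molecule") unique(h$molecule) else h$molecule
  }), use.names = FALSE)
  tab <- table(mols)
  out <- data.frame(molecule = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$molecule), , drop = FALSE]
  out$shown <- out$count >= display_min
  rownames(out) <- NULL
  out
}

#' Exact-membership intersection groups of per-cell-type molecule sets
#'
#' Reduces each cell type's hits to its unique-molecule set and partitions
#' the union of all molecules by the exact subset of cell types containing
#' each one (UpSet semantics). Groups are sorted by subset size
#' descending, then group size descending, then subset label.
#'
#' @param hits named list, cell type -> `ranked_hits`.
#' @return data.frame with columns `cell_types` (comma-joined subset
#'   label), `n_cell_types`, `size`, `molecules` (semicolon-joined).
#' @export
intersect_celltypes <- function(hits) {
  if (!length(hits)) stop("at least one cell type required")
  sets <- lapply(hits, function(h) unique(h$molecule))
  all_mols <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_mols %in% s,
                   logical(length(all_mols)))
  member <- matrix(member, nrow = length(all_mols),
                   dimnames = list(all_mols, names(sets)))
  key <- apply(member, 1, function(r)
    paste(colnames(member)[r], collapse = ","))
  groups <- split(all_mols, key)
  out <- data.frame(
    cell_types = names(groups),
    n_cell_types = vapply(strsplit(names(groups), ",", fixed = TRUE),
                          length, integer(1)),
    size = lengths(groups),
    molecules = vapply(groups, function(g) paste(sort(g), collapse = ";"),
                       character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$n_cell_types, -out$size, out$cell_types), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unique-molecule count and common-to-all molecule set
#'
#' @param hits named list, cell type -> `ranked_hits`.
#' @return list with `unique_count` (size of the union of per-cell-type
#'   molecule sets) and `common` (sorted intersection over all cell
#'   types).
#' @export
unique_and_common <- function(hits) {
  if (!length(hits)) stop("at least one cell type required")
  sets <- lapply(hits, function(h) unique(h$molecule))
  list(unique_count = length(unique(unlist(sets))),
       common = sort(Reduce(intersect, sets)))
}

#' Recovery of planted reversers from a pipeline bundle
#'
#' For each planted reverser, reports the best rank of any of its
#' experiments within its targeted cell type's hit list and whether that
#' rank lies within `top_n`; plus the summary fraction recovered.
#'
#' @param bundle a pipeline bundle from [repurpose_pipeline()].
#' @param truth the matching [syn_truth()].
#' @param top_n recovery window.
#' @return list with `per_reverser` (data.frame: drug, cell_type,
#'   best_rank, in_top_n) and `fraction_recovered`.
#' @export
evaluate_recovery <- function(bundle, truth, top_n = 50) {
  rv <- truth$planted_reversers
  if (!nrow(rv)) stop("truth contains no planted reversers")
  bank_mols <- bundle$bank_molecules
  rows <- lapply(seq_len(nrow(rv)), function(i) {
    drug <- rv$drug[i]; ct <- rv$cell_type[i]
    if (!drug %in% bank_mols)
      stop("planted drug not in the bank: ", drug)
    if (!ct %in% names(bundle$hits))
      stop("targeted cell type not in the bundle: ", ct)
    h <- bundle$hits[[ct]]
    r <- h$rank[h$molecule == drug]
    best <- if (length(r)) min(r) else NA_integer_
    data.frame(drug = drug, cell_type = ct, best_rank = best,
               in_top_n = !is.na(best) && best <= top_n,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_reverser = per, fraction_recovered = mean(per$in_top_n))
}

#' Planted-reverser recovery study over repeated seeds
#'
#' Runs the default synthetic scenario end to end once per seed (cohort
#' generation, QC, annotation, pseudobulk, PAL, query, reverse-mode
#' ranking) and evaluates how often the five planted reversers land in
#' the targeted cell type's top `top_n`. As a polarity control, the same
#' queries are also ranked in mimic mode, where the planted reversers
#' should do no better than decoys.
#'
#' @param seeds integer vector of scenario seeds.
#' @param top_n recovery window (default 10).
#' @param ... overrides forwarded to [default_scenario()].
#' @return data.frame with one row per seed: `seed`,
#'   `fraction_recovered`, `all_recovered`, `mimic_fraction`,
#'   `annotation_accuracy`, `mean_planted_pal`, `unique_molecules`,
#'   `n_common_to_all`.
#' @export
recovery_study <- function(seeds, top_n = 10, ...) {
  rows <- lapply(seeds, function(s) {
    sc <- default_scenario(seed = s, ...)
    b <- repurpose_pipeline(sc$matrix, sc$marker_sets, sc$db, sc$bank)
    rec <- evaluate_recovery(b, sc$truth, top_n = top_n)
    mimic_hits <- lapply(b$queries, function(q)
      rank_drugs(q, sc$bank, scorer = "overlap", mode = "mimic",
                 top_n = b$manifest$params$top_n))
    rec_m <- evaluate_recovery(list(hits = mimic_hits,
                                    bank_molecules = b$bank_molecules),
                               sc$truth, top_n = top_n)
    truth_lab <- sc$truth$cell_type_of_cell[b$annotation$barcode]
    planted_ids <- vapply(sc$truth$planted_effects,
                          function(p) p$pathway_id, character(1))
    target <- sc$truth$planted_effects[[1]]$cell_type
    ppal <- b$pal$pal[b$pal$cell_type == target &
                        b$pal$pathway %in% planted_ids]
    data.frame(seed = s,
               fraction_recovered = rec$fraction_recovered,
               all_recovered = rec$fraction_recovered == 1,
               mimic_fraction = rec_m$fraction_recovered,
               annotation_accuracy = mean(b$annotation$label == truth_lab),
               mean_planted_pal = mean(ppal),
               unique_molecules = b$unique_common$unique_count,
               n_common_to_all = length(b$unique_common$common))
  })
  do.call(rbind, rows)
}

default_params <- function() {
  list(min_features = 200, max_features = 2500, min_cells = 3,
       max_mito_pct = 10, max_hb_pct = 10, scale = 1e4,
       min_margin = 0.1, top_pathways = 10, max_per_side = 2000,
       scorer = "overlap", mode = "reverse", top_n = 50,
       display_min = 6)
}

#' Run the full repurposing analysis in memory
#'
#' Executes QC (cells, then genes), normalization, marker-score cell-type
#' annotation, per-(cell type, condition) geometric-mean pseudobulk, PAL
#' computation, top-pathway query construction, and reverse-mode drug
#' ranking for every annotated cell type with cells in both conditions,
#' followed by cross-cell-type aggregation. Cell types lacking one
#' condition after QC, or with no directional pathway, are skipped and
#' listed in the manifest. Fully deterministic given its inputs.
#'
#' @param m a [count_matrix()].
#' @param markers named list of marker gene sets.
#' @param db a [pathway_db()].
#' @param bank a [drug_bank()].
#' @param params named list overriding the defaults (QC thresholds
#'   200/2500/3 and <10 percent mito/hb, annotation margin 0.1, top 10
#'   pathways, overlap/reverse scoring, top 50 molecules).
#' @return a bundle: list with `qc`, `annotation`, `pal`, `queries`,
#'   `hits`, `occurrence`, `occurrence_by_molecule`, `intersections`,
#'   `unique_common`, `bank_molecules`, `manifest`.
#' @export
repurpose_pipeline <- function(m, markers, db, bank, params = list()) {
  p <- utils::modifyList(default_params(), params)
  n0 <- c(genes = nrow(m$counts), cells = ncol(m$counts))
  m <- filter_cells(m, p$min_features, p$max_features,
                    p$max_mito_pct, p$max_hb_pct)
  m <- filter_genes(m, p$min_cells)
  nm <- normalize_counts(m, p$scale)
  ann <- score_cell_types(nm, markers, p$min_margin)
  types <- sort(setdiff(unique(ann$label), "unassigned"))
  skipped <- character(0)
  profiles <- list()
  for (ct in types) {
    sel <- ann$label == ct
    conds <- unique(nm$cell_meta$condition[sel])
    if (!all(c("case", "control") %in% conds)) {
      skipped <- c(skipped, ct)
      next
    }
    profiles[[ct]] <- list(
      case = pseudobulk_geomean(nm, ann, ct, "case"),
      control = pseudobulk_geomean(nm, ann, ct, "control"))
  }
  pal <- pal_table(profiles, db)
  queries <- list(); hits <- list()
  for (ct in names(profiles)) {
    top <- top_pathways(pal, ct, p$top_pathways)
    if (!length(top$activated) && !length(top$inhibited)) {
      skipped <- c(skipped, ct)
      next
    }
    cnr <- compute_cnr(profiles[[ct]]$case, profiles[[ct]]$control)
    q <- build_query(top$activated, top$inhibited, db, cnr,
                     p$max_per_side, cell_type = ct)
    queries[[ct]] <- q
    hits[[ct]] <- rank_drugs(q, bank, scorer = p$scorer, mode = p$mode,
                             top_n = p$top_n)
  }
  if (!length(hits))
    stop("rank stage: no cell type produced a query (all skipped: ",
         paste(skipped, collapse = ", "), ")")
  list(qc = list(before = n0,
                 after = c(genes = nrow(m$counts), cells = ncol(m$counts))),
       annotation = ann,
       pal = pal,
       queries = queries,
       hits = hits,
       occurrence = occurrence_counts(hits, p$display_min),
       occurrence_by_molecule = occurrence_counts(hits, p$display_min,
                                                  level = "molecule"),
       intersections = intersect_celltypes(hits),
       unique_common = unique_and_common(hits),
       bank_molecules = unique(vapply(bank$experiments,
                                      function(e) e$molecule, character(1))),
       manifest = list(params = p, skipped_cell_types = unique(skipped),
                       normalization = "library-size log1p",
                       annotation = "marker z-score argmax",
                       n_pathways = length(db$pathways),
                       n_experiments = length(bank$experiments)))
}

#' Run the pipeline from a config file and write the report bundle
#'
#' The config (YAML path or equivalent named list) names the inputs and
#' optional parameter overrides:
#' \preformatted{
#' matrix_dir: path to the MTX triplet + cell_metadata.tsv
#' markers: marker TSV or GMT
#' pathways: pathway GMT
#' bank: drug bank GMT or JSON
#' params: {min_features: 200, ...}   # optional overrides
#' }
#' Outputs written to `out_dir`: `manifest.json`, `annotation.tsv`,
#' `pal.tsv`, per-cell-type `query_<type>.gmt`/`.json` and
#' `hits_<type>.tsv`, `occurrence.tsv`, `occurrence_by_molecule.tsv`,
#' `intersections.tsv`, `summary.json`. Reruns on identical inputs are
#' byte-identical.
#'
#' @param config YAML file path or named list.
#' @param out_dir output directory (created if needed).
#' @return the bundle from [repurpose_pipeline()], invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("matrix_dir", "markers", "pathways")) {
    if (is.null(config[[key]]))
      stop("config stage error: missing '", key, "'")
  }
  if (is.null(config$bank))
    stop("rank stage: config is missing 'bank'")
  m <- read_count_matrix(config$matrix_dir)
  markers <- read_markers(config$markers)
  db <- read_gmt(config$pathways)
  bank <- read_drug_bank(config$bank)
  params <- if (is.null(config$params)) list() else config$params
  bundle <- repurpose_pipeline(m, markers, db, bank, params)
  write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pipeline bundle to a directory of TSV/JSON/GMT files
#' @param bundle result of [repurpose_pipeline()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  write_tsv(bundle$annotation, f("annotation.tsv"))
  write_tsv(bundle$pal, f("pal.tsv"))
  for (ct in names(bundle$queries)) {
    write_query_gmt(bundle$queries[[ct]], f(sprintf("query_%s.gmt", ct)))
    write_query_json(bundle$queries[[ct]], f(sprintf("query_%s.json", ct)))
    write_tsv(bundle$hits[[ct]], f(sprintf("hits_%s.tsv", ct)))
  }
  write_tsv(bundle$occurrence, f("occurrence.tsv"))
  write_tsv(bundle$occurrence_by_molecule, f("occurrence_by_molecule.tsv"))
  write_tsv(bundle$intersections, f("intersections.tsv"))
  jsonlite::write_json(
    list(qc = as.list(bundle$qc), unique_molecules =
           bundle$unique_common$unique_count,
         common_to_all = bundle$unique_common$common),
    f("summary.json"), auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, f("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
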