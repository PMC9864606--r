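#' Write a count matrix as a 10x-style MTX triplet plus cell metadata
#'
#' Produces `matrix.mtx`, `features.tsv`, `barcodes.tsv` and
#' `cell_metadata.tsv` (columns barcode, donor, condition) in `dir`.
#'
#' @param m a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(m$counts), symbol = rownames(m$counts),
               type = "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(m$cell_meta[, c("barcode", "donor", "condition")],
                     file.path(dir, "cell_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix from a 10x-style MTX triplet plus cell metadata
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `cell_metadata.tsv`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  rownames(counts) <- feats[[1]]
  colnames(counts) <- barcodes
  meta <- utils::read.table(file.path(dir, "cell_metadata.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  count_matrix(counts, meta[match(barcodes, meta$barcode), , drop = FALSE])
}

#' Read marker sets from a two-column TSV or a GMT file
#'
#' TSV columns: `cell_type`, `gene` (header required). A `.gmt` file is
#' read with [read_gmt()], one set per cell type.
#'
#' @param path marker file.
#' @return named list, cell type -> character vector of marker genes.
#' @export
read_markers <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    db <- read_gmt(path)
    return(lapply(db$pathways, function(p) p$genes))
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(tab)))
    stop("marker TSV needs columns 'cell_type' and 'gene'")
  split(toupper(tab$gene), tab$cell_type)
}

#' Write marker sets as a two-column TSV
#' @param markers named list, cell type -> genes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  tab <- data.frame(cell_type = rep(names(markers), lengths(markers)),
                    gene = unlist(markers, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a drug bank as paired-GMT or JSON
#'
#' GMT: two lines per experiment, IDs suffixed "-UP" / "-DN", with the
#' description field holding `molecule|cell_line|dose`. JSON: a faithful
#' dump of experiments, gene universe and metadata.
#'
#' @param bank a [drug_bank()].
#' @param path output path; format chosen by extension (`.json` vs GMT
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_drug_bank <- function(bank, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(experiments = lapply(unname(bank$experiments), function(e)
        list(exp_id = e$exp_id, molecule = e$molecule,
             cell_line = e$cell_line, dose = e$dose,
             up = e$up, down = e$down)),
        gene_universe = bank$gene_universe,
        metadata = bank$metadata),
      path, auto_unbox = TRUE)
    return(invisible(path))
  }
  lines <- unlist(lapply(bank$experiments, function(e) {
    desc <- paste(e$molecule, e$cell_line, e$dose, sep = "|")
    c(paste(c(paste0(e$exp_id, "-UP"), desc, e$up), collapse = "\t"),
      paste(c(paste0(e$exp_id, "-DN"), desc, e$down), collapse = "\t"))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug bank from paired-GMT or JSON
#'
#' @param path bank file (`.json`, or GMT with "-UP"/"-DN" suffixed
#'   paired lines).
#' @return a [drug_bank()].
#' @export
read_drug_bank <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
    exps <- lapply(j$experiments, function(e)
      list(exp_id = e$exp_id, molecule = e$molecule,
           cell_line = e$cell_line, dose = e$dose,
           up = as.character(unlist(e$up)),
           down = as.character(unlist(e$down))))
    return(drug_bank(exps, gene_universe = as.character(j$gene_universe),
                     metadata = j$metadata))
  }
  db <- read_gmt(path)
  ids <- names(db$pathways)
  bare <- sub("-(UP|DN)$", "", ids)
  side <- sub("^.*-(UP|DN)$", "\\1", ids)
  if (!all(grepl("-(UP|DN)$", ids)))
    stop("drug-bank GMT lines must end in -UP or -DN")
  exps <- lapply(unique(bare), function(b) {
    up_i <- which(bare == b & side == "UP")
    dn_i <- which(bare == b & side == "DN")
    if (length(up_i) != 1 || length(dn_i) != 1)
      stop("experiment ", b, " must have exactly one -UP and one -DN line")
    meta <- strsplit(db$pathways[[up_i]]$description, "|", fixed = TRUE)[[1]]
    list(exp_id = b,
         molecule = if (length(meta) >= 1) meta[1] else b,
         cell_line = if (length(meta) >= 2) meta[2] else "NA",
         dose = if (length(meta) >= 3) meta[3] else "NA",
         up = db$pathways[[up_i]]$genes,
         down = db$pathways[[dn_i]]$genes)
  })
  drug_bank(exps)
}

#' Write synthetic ground truth as JSON
#' @param truth a [syn_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(planted_effects = lapply(truth$planted_effects, function(p)
      list(pathway_id = p$pathway_id, cell_type = p$cell_type,
           log2_fold = p$log2_fold)),
      planted_reversers = truth$planted_reversers,
      cell_type_of_cell = as.list(truth$cell_type_of_cell),
      low_quality = truth$low_quality),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read synthetic ground truth from JSON
#' @param path truth JSON written by [write_truth()].
#' @return a [syn_truth()].
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  effects <- lapply(j$planted_effects, function(p)
    planted_effect(p$pathway_id, p$cell_type, p$log2_fold))
  rev <- as.data.frame(do.call(rbind, lapply(j$planted_reversers, function(r)
    data.frame(drug = r$drug, cell_type = r$cell_type,
               stringsAsFactors = FALSE))))
  if (is.null(rev) || !nrow(rev))
    rev <- data.frame(drug = character(0), cell_type = character(0))
  syn_truth(planted_effects = effects, planted_reversers = rev,
            cell_type_of_cell = unlist(j$cell_type_of_cell),
            low_quality = as.character(unlist(j$low_quality)))
}
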