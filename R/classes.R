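#' Construct a gene-by-cell count matrix with cell metadata
#'
#' The central container of the pipeline: sparse non-negative integer
#' counts (genes in rows, cells in columns) plus per-cell donor and
#' condition labels. Gene identifiers are case-normalized to upper case on
#' construction so that downstream set operations (markers, pathways, drug
#' signatures) match case-insensitively.
#'
#' @param counts matrix or Matrix of non-negative integer counts with gene
#'   IDs as rownames and cell IDs as colnames.
#' @param cell_meta data.frame with one row per cell, columns `barcode`,
#'   `donor`, `condition` (`condition` must be "case" or "control").
#'   Row order must match the columns of `counts`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (dgCMatrix) and `cell_meta`.
#' @export
as_sparse <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  x <- methods::as(methods::as(methods::as(x, "dMatrix"),
                               "generalMatrix"), "CsparseMatrix")
  # a zero-extent axis cannot hold names; treat it as validly named
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x))))
    stop("matrix must carry gene rownames and cell colnames")
  x
}

count_matrix <- function(counts, cell_meta) {
  counts <- as_sparse(counts)
  if (nrow(counts) > 0) rownames(counts) <- toupper(rownames(counts))
  if (anyDuplicated(rownames(counts)))
    stop("gene IDs not unique after case normalization")
  if (anyDuplicated(colnames(counts)))
    stop("cell IDs not unique")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  cell_meta <- validate_cell_meta(cell_meta, colnames(counts))
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "count_matrix")
}

validate_cell_meta <- function(cell_meta, cell_ids) {
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  need <- c("barcode", "donor", "condition")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss))
    stop("cell_meta missing column(s): ", paste(miss, collapse = ", "))
  if (!identical(as.character(cell_meta$barcode), as.character(cell_ids)))
    stop("cell_meta barcodes do not match count matrix cells")
  bad <- setdiff(unique(cell_meta$condition), c("case", "control"))
  if (length(bad))
    stop("condition labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  rownames(cell_meta) <- cell_meta$barcode
  cell_meta
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d case, %d control cells)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$cell_meta$condition == "case"),
              sum(x$cell_meta$condition == "control")))
  invisible(x)
}

#' Construct a normalized expression matrix
#'
#' Same axes and metadata as [count_matrix()], holding non-negative real
#' values (log1p of library-size-scaled counts). Usually produced by
#' [normalize_counts()], not by hand.
#'
#' @param values gene-by-cell Matrix of non-negative reals.
#' @param cell_meta per-cell metadata as for [count_matrix()].
#' @return An object of class `norm_matrix`.
#' @export
norm_matrix <- function(values, cell_meta) {
  values <- as_sparse(values)
  if (any(values@x < 0)) stop("normalized values must be non-negative")
  if (nrow(values) > 0) rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("gene IDs not unique after case normalization")
  cell_meta <- validate_cell_meta(cell_meta, colnames(values))
  structure(list(values = values, cell_meta = cell_meta),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a pseudobulk expression profile
#'
#' Per-(cell type, condition) vector of geometric-mean aggregated
#' expression. `gm[g] >= 1` for every gene, with equality exactly when the
#' gene is zero in all contributing cells.
#'
#' @param cell_type,condition labels of the aggregated cell group.
#' @param gm named numeric vector, one value >= 1 per gene.
#' @param n_cells number of contributing cells (positive).
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(cell_type, condition, gm, n_cells) {
  if (is.null(names(gm))) stop("gm must be a named gene vector")
  names(gm) <- toupper(names(gm))
  if (anyDuplicated(names(gm)))
    stop("gene IDs not unique after case normalization")
  if (any(gm < 1 - 1e-12)) stop("geometric-mean values must be >= 1")
  if (n_cells < 1) stop("n_cells must be positive")
  structure(list(cell_type = cell_type, condition = condition,
                 gm = gm, n_cells = as.integer(n_cells)),
            class = "expression_profile")
}

#' Construct a pathway database
#'
#' Named gene sets with per-gene activator/repressor roles (ARR: +1
#' activator, -1 repressor, 0 neutral) and a free-text category label.
#'
#' @param pathways named list; each element a list with `genes` (character),
#'   `arr` (named numeric in \{-1, 0, 1\}, names = genes) and optional
#'   `category` and `description` strings.
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(pathways) {
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)))
    stop("pathway IDs must be unique and named")
  pathways <- lapply(pathways, function(p) {
    p$genes <- toupper(p$genes)
    if (anyDuplicated(p$genes)) stop("duplicate genes within a pathway")
    if (is.null(p$arr)) {
      p$arr <- stats::setNames(rep(1, length(p$genes)), p$genes)
    } else {
      names(p$arr) <- toupper(names(p$arr))
      p$arr <- p$arr[p$genes]
    }
    if (!all(p$arr %in% c(-1, 0, 1)))
      stop("ARR weights must be -1, 0 or +1")
    if (!any(p$arr != 0))
      stop("each pathway needs at least one gene with nonzero ARR weight")
    if (is.null(p$category)) p$category <- "uncategorized"
    if (is.null(p$description)) p$description <- p$category
    p
  })
  structure(list(pathways = pathways), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  sizes <- vapply(x$pathways, function(p) length(p$genes), integer(1))
  cat(sprintf("pathway_db: %d pathways, %d-%d genes each\n",
              length(x$pathways), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.pathway_db <- function(x) length(x$pathways)

#' Construct a drug-signature bank
#'
#' A list of perturbation experiments, each with a molecule name,
#' cell-line and dose tags, and disjoint up/down gene sets. One molecule
#' may own several experiments (different doses or cell lines).
#'
#' @param experiments list of lists with elements `exp_id`, `molecule`,
#'   `cell_line`, `dose`, `up` (character), `down` (character).
#' @param gene_universe optional character vector of all genes the bank
#'   draws from; defaults to the union of all signature genes.
#' @param metadata optional list of bank-level annotations (e.g. pad
#'   fractions recorded by the synthetic generator).
#' @return An object of class `drug_bank`.
#' @export
drug_bank <- function(experiments, gene_universe = NULL, metadata = list()) {
  ids <- vapply(experiments, function(e) e$exp_id, character(1))
  if (anyDuplicated(ids)) stop("experiment IDs must be unique")
  experiments <- lapply(experiments, function(e) {
    if (is.null(e$molecule) || !nzchar(e$molecule))
      stop("molecule names must be non-empty")
    e$up <- unique(toupper(e$up))
    e$down <- unique(toupper(e$down))
    if (length(intersect(e$up, e$down)))
      stop("experiment ", e$exp_id, ": up and down sets overlap")
    if (is.null(e$cell_line)) e$cell_line <- "NA"
    if (is.null(e$dose)) e$dose <- "NA"
    e
  })
  names(experiments) <- ids
  if (is.null(gene_universe))
    gene_universe <- sort(unique(unlist(lapply(experiments,
                                               function(e) c(e$up, e$down)))))
  structure(list(experiments = experiments,
                 gene_universe = toupper(gene_universe),
                 metadata = metadata),
            class = "drug_bank")
}

#' @export
print.drug_bank <- function(x, ...) {
  mols <- unique(vapply(x$experiments, function(e) e$molecule, character(1)))
  cat(sprintf("drug_bank: %d experiments, %d molecules\n",
              length(x$experiments), length(mols)))
  invisible(x)
}

#' @export
length.drug_bank <- function(x) length(x$experiments)

#' Construct an up/down query signature
#'
#' The pathway-derived query for one cell type: ordered up- and
#' down-regulated gene lists (disjoint by construction) plus provenance
#' mapping each gene to the top pathways that contributed it.
#'
#' @param cell_type label of the queried cell type.
#' @param up,down character vectors of gene IDs, disjoint.
#' @param provenance named list mapping gene -> contributing pathway IDs.
#' @return An object of class `query_signature`.
#' @export
query_signature <- function(cell_type, up, down, provenance = list()) {
  up <- toupper(up); down <- toupper(down)
  if (length(intersect(up, down)))
    stop("up and down query sides must be disjoint")
  structure(list(cell_type = cell_type, up = up, down = down,
                 provenance = provenance),
            class = "query_signature")
}

#' @export
print.query_signature <- function(x, ...) {
  cat(sprintf("query_signature [%s]: %d up, %d down genes\n",
              x$cell_type, length(x$up), length(x$down)))
  invisible(x)
}
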