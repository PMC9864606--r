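#' Per-cell QC metrics
#'
#' Detected-gene counts and mitochondrial / hemoglobin count percentages.
#' Mitochondrial genes are identified by the case-insensitive symbol
#' prefix "MT-", hemoglobin genes by the regex `^HB[ABDEGMQZ]`.
#'
#' @param m a [count_matrix()].
#' @return data.frame with columns `barcode`, `n_detected`, `total`,
#'   `mito_pct`, `hb_pct`.
#' @export
cell_qc_metrics <- function(m) {
  counts <- m$counts
  total <- Matrix::colSums(counts)
  is_mito <- grepl("^MT-", rownames(counts))
  is_hb <- grepl("^HB[ABDEGMQZ]", rownames(counts))
  pct <- function(sel) {
    s <- if (any(sel)) Matrix::colSums(counts[sel, , drop = FALSE]) else 0
    ifelse(total > 0, 100 * s / total, 0)
  }
  data.frame(barcode = colnames(counts),
             n_detected = Matrix::colSums(counts > 0),
             total = total,
             mito_pct = pct(is_mito),
             hb_pct = pct(is_hb),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter cells on detected genes and mitochondrial/hemoglobin content
#'
#' Retains exactly the cells whose detected-gene count lies in
#' `[min_features, max_features]` (inclusive) and whose mitochondrial and
#' hemoglobin count percentages are strictly below the respective
#' thresholds. The gene axis is unchanged.
#'
#' @param m a [count_matrix()].
#' @param min_features,max_features inclusive bounds on the number of
#'   genes detected (count > 0) per cell.
#' @param max_mito_pct,max_hb_pct strict upper bounds (percent) on
#'   mitochondrial / hemoglobin content.
#' @return the filtered [count_matrix()].
#' @export
filter_cells <- function(m, min_features = 200, max_features = 2500,
                         max_mito_pct = 10, max_hb_pct = 10) {
  stopifnot(min_features >= 0, max_mito_pct >= 0, max_hb_pct >= 0)
  if (min_features > max_features)
    stop("min_features must not exceed max_features")
  qc <- cell_qc_metrics(m)
  keep <- qc$n_detected >= min_features & qc$n_detected <= max_features &
    qc$mito_pct < max_mito_pct & qc$hb_pct < max_hb_pct
  count_matrix(m$counts[, keep, drop = FALSE],
               m$cell_meta[keep, , drop = FALSE])
}

#' Filter genes on the number of cells detecting them
#'
#' Retains genes with count > 0 in at least `min_cells` cells; the cell
#' axis is unchanged.
#'
#' @param m a [count_matrix()].
#' @param min_cells minimum number of detecting cells (>= 0).
#' @return the filtered [count_matrix()].
#' @export
filter_genes <- function(m, min_cells = 3) {
  stopifnot(min_cells >= 0)
  keep <- Matrix::rowSums(m$counts > 0) >= min_cells
  count_matrix(m$counts[keep, , drop = FALSE], m$cell_meta)
}

#' Library-size normalization with log1p transform
#'
#' value(g, c) = log(1 + scale * count(g, c) / total(c)). Zero counts map
#' to zero, so sparsity is preserved. Every cell must have a positive
#' total count (run [filter_cells()] first).
#'
#' @param m a [count_matrix()].
#' @param scale library-size scale factor.
#' @return a [norm_matrix()].
#' @export
normalize_counts <- function(m, scale = 1e4) {
  total <- Matrix::colSums(m$counts)
  if (any(total == 0))
    stop("cells with zero total count present; filter cells first")
  v <- m$counts %*% Matrix::Diagonal(x = scale / total)
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$counts)
  norm_matrix(v, m$cell_meta)
}

#' Geometric-mean pseudobulk profile for one (cell type, condition) group
#'
#' Aggregates all cells annotated with `cell_type` under `condition` into
#' a single per-gene profile: gm(g) = exp(mean over cells of
#' log(1 + value(g, c))). The +1 pseudocount keeps genes that are zero in
#' every contributing cell well-defined at gm = 1 (log-ratio 0
#' downstream).
#'
#' @param nm a [norm_matrix()].
#' @param annotation a cell annotation as returned by
#'   [score_cell_types()] (data.frame with `barcode`, `label`).
#' @param cell_type,condition the group to aggregate.
#' @return an [expression_profile()].
#' @export
pseudobulk_geomean <- function(nm, annotation, cell_type, condition) {
  lab <- annotation$label[match(colnames(nm$values), annotation$barcode)]
  sel <- !is.na(lab) & lab == cell_type & nm$cell_meta$condition == condition
  if (!any(sel))
    stop("no cells in group (", cell_type, ", ", condition, ")")
  v <- nm$values[, sel, drop = FALSE]
  v@x <- log1p(v@x)
  gm <- exp(Matrix::rowMeans(v))
  expression_profile(cell_type, condition,
                     stats::setNames(as.numeric(gm), rownames(nm$values)),
                     n_cells = sum(sel))
}
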