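#' Assign cells to cell types by marker-set scoring
#'
#' For each cell, score(t) is the mean z-scored (per gene, across all
#' cells) normalized expression over the markers of type t. A cell is
#' labeled with the argmax type when the margin (best minus second-best
#' score) is at least `min_margin`, otherwise "unassigned". Exact score
#' ties resolve to the lexicographically smallest label, which then has
#' margin 0 and is therefore unassigned unless `min_margin = 0`. Genes
#' with zero variance contribute z = 0, so adding an all-zero gene never
#' changes a score.
#'
#' @param nm a [norm_matrix()].
#' @param markers named list, cell type -> marker gene IDs. Markers absent
#'   from the matrix are dropped with a warning; a type with no marker
#'   present is an error.
#' @param min_margin minimum best-minus-second score gap for assignment.
#' @return data.frame with columns `barcode`, `label`, `margin`, one row
#'   per cell in matrix order.
#' @export
score_cell_types <- function(nm, markers, min_margin = 0.1) {
  if (!length(markers) || is.null(names(markers)))
    stop("markers must be a named list of gene sets")
  markers <- lapply(markers, toupper)
  present <- lapply(markers, function(g) intersect(g, rownames(nm$values)))
  empty <- names(present)[lengths(present) == 0]
  if (length(empty))
    stop("no marker present in the matrix for type(s): ",
         paste(empty, collapse = ", "))
  n_drop <- sum(lengths(markers)) - sum(lengths(present))
  if (n_drop > 0)
    warning(n_drop, " marker gene(s) absent from the matrix were dropped")
  used <- unique(unlist(present))
  x <- as.matrix(nm$values[used, , drop = FALSE])
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  scores <- do.call(rbind, lapply(present, function(g)
    colMeans(z[g, , drop = FALSE])))  # types x cells
  types <- sort(rownames(scores))
  scores <- scores[types, , drop = FALSE]
  lab <- character(ncol(scores)); marg <- numeric(ncol(scores))
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    best <- which(s == max(s))[1]  # types sorted, so ties -> smallest label
    second <- if (length(s) > 1) max(s[-best]) else -Inf
    marg[j] <- s[best] - second
    lab[j] <- if (marg[j] >= min_margin) types[best] else "unassigned"
  }
  data.frame(barcode = colnames(nm$values), label = lab, margin = marg,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Two-sided Wilcoxon rank-sum p-value.
# Group sizes <= `exact_max` on both sides: exact enumeration of all
# C(n+m, n) assignments of the observed (mid)ranks, p = P(|W - E[W]| >=
# |w_obs - E[W]|) under the permutation null (handles ties exactly).
# Larger groups: stats::wilcox.test normal approximation with tie
# correction and continuity correction.
wilcox_p <- function(x, y, exact_max = 8) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both groups must be non-empty")
  if (n <= exact_max && m <= exact_max) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n)])
    ew <- n * (n + m + 1) / 2
    combos <- utils::combn(n + m, n)
    w_all <- colSums(matrix(r[combos], nrow = n))
    mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE)$p.value)
  }
}

#' Detect marker genes of one cluster (one-vs-rest Wilcoxon)
#'
#' For every gene, in-cluster cells are compared against all other cells
#' by a two-sided Wilcoxon rank-sum test on normalized values (exact
#' enumeration when both groups have at most 8 cells, tie- and
#' continuity-corrected normal approximation otherwise). The fold change
#' is log2((mean_in + eps) / (mean_out + eps)) with eps = 1e-9, and
#' pct_in / pct_out are the nonzero fractions per group. Reported rows
#' satisfy log2FC >= `min_log2fc`, p <= `alpha`, and max(pct_in, pct_out)
#' >= `min_pct`, sorted by ascending p, then descending log2FC, then gene
#' ID. P-values are raw by default; set `fdr = TRUE` for
#' Benjamini-Hochberg adjustment before the `alpha` cut.
#'
#' @param nm a [norm_matrix()].
#' @param annotation data.frame with `barcode`, `label` (from
#'   [score_cell_types()]).
#' @param cluster the cluster label to profile.
#' @param min_log2fc,alpha,min_pct reporting thresholds.
#' @param fdr apply BH correction to p-values before thresholding.
#' @return data.frame with columns `gene`, `cluster`, `log2fc`, `p`,
#'   `pct_in`, `pct_out`.
#' @export
find_markers <- function(nm, annotation, cluster, min_log2fc = 0.25,
                         alpha = 0.01, min_pct = 0.3, fdr = FALSE) {
  lab <- annotation$label[match(colnames(nm$values), annotation$barcode)]
  in_cl <- !is.na(lab) & lab == cluster
  if (!any(in_cl)) stop("cluster '", cluster, "' is empty")
  if (all(in_cl)) stop("no out-of-cluster cells")
  x <- nm$values[, in_cl, drop = FALSE]
  y <- nm$values[, !in_cl, drop = FALSE]
  eps <- 1e-9
  mean_in <- Matrix::rowMeans(x)
  mean_out <- Matrix::rowMeans(y)
  log2fc <- log2((mean_in + eps) / (mean_out + eps))
  pct_in <- Matrix::rowMeans(x > 0)
  pct_out <- Matrix::rowMeans(y > 0)
  # test only genes that can pass the reporting thresholds
  cand <- which(log2fc >= min_log2fc & pmax(pct_in, pct_out) >= min_pct)
  p <- rep(NA_real_, nrow(x))
  for (i in cand)
    p[i] <- wilcox_p(as.numeric(x[i, ]), as.numeric(y[i, ]))
  if (fdr) p[cand] <- stats::p.adjust(p[cand], method = "BH")
  keep <- cand[p[cand] <= alpha]
  res <- data.frame(gene = rownames(x)[keep],
                    cluster = rep(cluster, length(keep)),
                    log2fc = log2fc[keep], p = p[keep],
                    pct_in = pct_in[keep], pct_out = pct_out[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p, -res$log2fc, res$gene), , drop = FALSE]
}
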