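#' Read a pathway database from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `ID<TAB>description<TAB>gene1<TAB>gene2...`. An extended dialect
#' encodes activator/repressor roles as `gene^+1` / `gene^-1` (and
#' `gene^0` for neutral); plain gene tokens default to ARR +1. Duplicate
#' genes within a line are deduplicated keeping the first weight;
#' duplicate pathway IDs are an error. The description field is kept as
#' both description and category label.
#'
#' @param path GMT file path.
#' @return a [pathway_db()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  paths <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    id <- f[1]
    if (id %in% names(paths)) stop("duplicate pathway ID: ", id)
    tokens <- f[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    has_w <- grepl("\\^[+-]?[01]$", tokens)
    genes <- ifelse(has_w, sub("\\^[+-]?[01]$", "", tokens), tokens)
    w <- ifelse(has_w, as.numeric(sub("^.*\\^", "", tokens)), 1)
    first <- !duplicated(toupper(genes))
    genes <- toupper(genes[first]); w <- w[first]
    paths[[id]] <- list(genes = genes,
                        arr = stats::setNames(w, genes),
                        category = f[2], description = f[2])
  }
  pathway_db(paths)
}

#' Write a pathway database to GMT
#'
#' Weights are written in the `gene^+1` dialect when any ARR differs from
#' +1 (or always, with `weights = TRUE`), so write -> read round-trips.
#'
#' @param db a [pathway_db()].
#' @param path output file path.
#' @param weights `"auto"` (default), `TRUE` or `FALSE`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path, weights = "auto") {
  lines <- vapply(names(db$pathways), function(id) {
    p <- db$pathways[[id]]
    wanted <- isTRUE(weights) ||
      (identical(weights, "auto") && any(p$arr != 1))
    toks <- if (wanted)
      sprintf("%s^%+d", p$genes, as.integer(p$arr[p$genes])) else p$genes
    paste(c(id, p$description, toks), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Case-to-normal ratio of two pseudobulk profiles
#'
#' CNR(g) = gm_case(g) / gm_control(g). Both profiles have gm >= 1, so
#' every ratio is finite and positive; a gene absent (zero) in both
#' conditions gives CNR = 1.
#'
#' @param case,control [expression_profile()]s over the same gene axis.
#' @return named positive numeric vector (the CNR per gene).
#' @export
compute_cnr <- function(case, control) {
  if (!setequal(names(case$gm), names(control$gm)))
    stop("profiles have mismatched gene axes")
  ctl <- control$gm[names(case$gm)]
  case$gm / ctl
}

#' Pathway activation level of one pathway
#'
#' PAL = 100 * sum_g ARR(g) * log2(CNR(g)) / sum_g |ARR(g)|, over the
#' pathway genes present in `cnr` (absent genes are skipped and counted).
#' A pathway with no evaluable gene (none present, or all present genes
#' neutral) is not an error: it returns `pal = NA` and is excluded from
#' ranking.
#'
#' @param cnr named CNR vector from [compute_cnr()].
#' @param pathway one element of a [pathway_db()] (list with `genes`,
#'   `arr`).
#' @return list with `pal` (real or NA) and `n_genes_used` (genes present
#'   with nonzero ARR).
#' @export
compute_pal <- function(cnr, pathway) {
  g <- intersect(pathway$genes, names(cnr))
  arr <- pathway$arr[g]
  used <- sum(arr != 0)
  denom <- sum(abs(arr))
  if (used == 0)
    return(list(pal = NA_real_, n_genes_used = 0L))
  pal <- 100 * sum(arr * log2(cnr[g])) / denom
  list(pal = as.numeric(pal), n_genes_used = as.integer(used))
}

#' PAL table across cell types and pathways
#'
#' Computes the case-to-normal ratio and PAL for every pathway in every
#' cell type with both condition profiles available. Pathways with no
#' evaluable gene are omitted (not rankable).
#'
#' @param profiles named list: cell type -> list(case =, control =
#'   [expression_profile()]).
#' @param db a [pathway_db()].
#' @return data.frame with columns `cell_type`, `pathway`, `pal`,
#'   `n_genes_used`, sorted by cell type then pathway ID.
#' @export
pal_table <- function(profiles, db) {
  rows <- list()
  for (ct in names(profiles)) {
    cnr <- compute_cnr(profiles[[ct]]$case, profiles[[ct]]$control)
    for (id in names(db$pathways)) {
      r <- compute_pal(cnr, db$pathways[[id]])
      if (!is.na(r$pal))
        rows[[length(rows) + 1L]] <-
          data.frame(cell_type = ct, pathway = id, pal = r$pal,
                     n_genes_used = r$n_genes_used,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cell_type = character(0), pathway = character(0),
                      pal = numeric(0), n_genes_used = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_type, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top activated and inhibited pathways of one cell type
#'
#' Activated: up to `k` pathways with the largest PAL among those with
#' PAL > 0, in descending order. Inhibited: up to `k` with the smallest
#' PAL among those with PAL < 0, ascending. Ties break by pathway ID
#' ascending; either list may be shorter than `k` (empty when no pathway
#' has the matching sign).
#'
#' @param pal a PAL table from [pal_table()].
#' @param cell_type the cell type to select for.
#' @param k list length cap (>= 1).
#' @return list with `activated` and `inhibited` (character vectors of
#'   pathway IDs).
#' @export
top_pathways <- function(pal, cell_type, k = 10) {
  stopifnot(k >= 1)
  p <- pal[pal$cell_type == cell_type, , drop = FALSE]
  up <- p[p$pal > 0, , drop = FALSE]
  up <- up[order(-up$pal, up$pathway), , drop = FALSE]
  dn <- p[p$pal < 0, , drop = FALSE]
  dn <- dn[order(dn$pal, dn$pathway), , drop = FALSE]
  list(activated = utils::head(up$pathway, k),
       inhibited = utils::head(dn$pathway, k))
}
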