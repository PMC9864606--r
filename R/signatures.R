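#' Build the up/down query signature from top pathway lists
#'
#' up = union of genes of the activated pathways, down = union of genes of
#' the inhibited pathways. A gene occurring in both unions is assigned to
#' the side matching the sign of its own log2 CNR and dropped entirely
#' when that log-ratio is zero, so the query always agrees with the
#' measured direction. Each side is ordered by descending |log2 CNR|
#' (ties by gene ID) and truncated to `max_per_side`. Genes absent from
#' `cnr` carry log-ratio 0 for ordering and conflict resolution.
#'
#' @param activated,inhibited character vectors of pathway IDs, as
#'   returned by [top_pathways()] for one cell type.
#' @param db a [pathway_db()].
#' @param cnr named CNR vector for the same cell type.
#' @param max_per_side cap on genes per query side.
#' @param cell_type label stored on the signature.
#' @return a [query_signature()] with per-gene provenance (contributing
#'   pathway IDs).
#' @export
build_query <- function(activated, inhibited, db, cnr,
                        max_per_side = 2000, cell_type = "all") {
  if (!length(activated) && !length(inhibited))
    stop("empty signature: no activated and no inhibited pathways")
  missing <- setdiff(c(activated, inhibited), names(db$pathways))
  if (length(missing))
    stop("unknown pathway ID(s): ", paste(missing, collapse = ", "))
  genes_of <- function(ids) unique(unlist(lapply(ids, function(id)
    db$pathways[[id]]$genes)))
  up <- genes_of(activated)
  dn <- genes_of(inhibited)
  l2 <- function(g) {
    v <- rep(0, length(g))
    hit <- g %in% names(cnr)
    v[hit] <- log2(cnr[g[hit]])
    stats::setNames(v, g)
  }
  both <- intersect(up, dn)
  if (length(both)) {
    d <- l2(both)
    up <- c(setdiff(up, both), both[d > 0])
    dn <- c(setdiff(dn, both), both[d < 0])
  }
  order_side <- function(g) {
    if (!length(g)) return(character(0))
    d <- l2(g)
    g[order(-abs(d), g)][seq_len(min(length(g), max_per_side))]
  }
  prov <- list()
  for (id in c(activated, inhibited))
    for (g in db$pathways[[id]]$genes)
      prov[[g]] <- c(prov[[g]], id)
  query_signature(cell_type, order_side(up), order_side(dn),
                  provenance = prov)
}

#' Write a query signature as a two-line GMT
#'
#' Lines `<celltype>-UP` and `<celltype>-DN`, genes in query order.
#'
#' @param q a [query_signature()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_query_gmt <- function(q, path) {
  writeLines(c(paste(c(paste0(q$cell_type, "-UP"), "query", q$up),
                     collapse = "\t"),
               paste(c(paste0(q$cell_type, "-DN"), "query", q$down),
                     collapse = "\t")),
             path)
  invisible(path)
}

#' Write a query signature with provenance as JSON
#'
#' @param q a [query_signature()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_query_json <- function(q, path) {
  jsonlite::write_json(list(cell_type = q$cell_type, up = q$up,
                            down = q$down, provenance = q$provenance),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
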