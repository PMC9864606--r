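#' Directional set-overlap score between a query and a drug experiment
#'
#' Reverse mode rewards drugs whose signature opposes the query:
#' score = (|q.up n d.down| + |q.down n d.up|) / (|q.up| + |q.down|).
#' Mimic mode rewards agreement:
#' score = (|q.up n d.up| + |q.down n d.down|) / (|q.up| + |q.down|).
#' Intersections are on case-normalized gene IDs; the score lies in
#' [0, 1] and equals 1 exactly when both query sides are fully covered by
#' the matching drug sides.
#'
#' @param q a [query_signature()] with at least one gene.
#' @param d one experiment of a [drug_bank()] (list with `up`, `down`).
#' @param mode `"reverse"` or `"mimic"`.
#' @return the score (single numeric).
#' @export
overlap_score <- function(q, d, mode = c("reverse", "mimic")) {
  mode <- match.arg(mode)
  det <- overlap_detail(q, d)
  n_query <- length(q$up) + length(q$down)
  if (n_query == 0) stop("query signature is empty")
  if (mode == "reverse") (det[["q_up_d_dn"]] + det[["q_dn_d_up"]]) / n_query
  else (det[["q_up_d_up"]] + det[["q_dn_d_dn"]]) / n_query
}

overlap_detail <- function(q, d) {
  d_up <- toupper(d$up); d_dn <- toupper(d$down)
  c(q_up_d_dn = length(intersect(q$up, d_dn)),
    q_dn_d_up = length(intersect(q$down, d_up)),
    q_up_d_up = length(intersect(q$up, d_up)),
    q_dn_d_dn = length(intersect(q$down, d_dn)))
}

# Weighted-KS enrichment score of gene set `s` in an ordered gene list:
# running sum +1/s at hits, -1/(N - s) at misses; ES is the extremum of
# the running sum (largest |value|; positive preferred on an exact
# magnitude tie). Genes of `s` absent from the list are ignored; a fully
# absent set scores 0 with a warning.
ks_es <- function(s, ranked_list) {
  s <- toupper(s); ranked_list <- toupper(ranked_list)
  hit <- ranked_list %in% s
  n_hit <- sum(hit)
  n <- length(ranked_list)
  if (n_hit == 0) {
    warning("gene set fully absent from the ranked list; ES = 0")
    return(0)
  }
  if (n_hit == n) stop("gene set covers the whole ranked list")
  # integer-scaled walk (x s*(N-s)) so the extremum is exact
  run <- cumsum(ifelse(hit, n - n_hit, -n_hit))
  hi <- max(run); lo <- min(run)
  es <- if (abs(hi) >= abs(lo)) hi else lo
  es / (n_hit * (n - n_hit))
}

#' Weighted-KS connectivity of a query against an ordered gene list
#'
#' The classic connectivity-map statistic: connectivity =
#' (ES(q.up) - ES(q.down)) / 2, where ES is the signed extremum of the
#' running-sum enrichment walk of each query side in `ranked_list`. A
#' value near -1 means the list places the query's up-genes at its bottom
#' and down-genes at its top (strong reversal); reverse-mode ranking
#' therefore sorts ascending.
#'
#' @param q a [query_signature()].
#' @param ranked_list ordered character vector of genes (most up-regulated
#'   by the perturbation first).
#' @return connectivity score in [-1, 1].
#' @export
ks_connectivity <- function(q, ranked_list) {
  es_up <- if (length(q$up)) ks_es(q$up, ranked_list) else 0
  es_dn <- if (length(q$down)) ks_es(q$down, ranked_list) else 0
  (es_up - es_dn) / 2
}

# Deterministic embedding of a set-valued experiment into an ordered
# list for the KS engine: up genes first, then the rest of the bank's
# gene universe, then down genes, each block alphabetical.
experiment_ranked_list <- function(d, gene_universe) {
  mid <- sort(setdiff(gene_universe, c(d$up, d$down)))
  c(sort(d$up), mid, sort(d$down))
}

#' Score and rank every experiment of a drug bank against a query
#'
#' Scores each experiment with the chosen engine and polarity, sorts
#' (overlap: descending score; KS reverse: ascending connectivity; KS
#' mimic: descending), breaks ties by experiment ID ascending, and
#' truncates. Ranking is experiment-level: one molecule may occupy
#' several rows (different doses/cell lines); `unique_molecules = TRUE`
#' instead keeps the first occurrence per molecule.
#'
#' @param q a [query_signature()].
#' @param bank a [drug_bank()] (non-empty).
#' @param scorer `"overlap"` or `"ks"`.
#' @param mode `"reverse"` or `"mimic"`.
#' @param top_n rows kept after sorting.
#' @param unique_molecules truncate to first occurrence per molecule.
#' @return data.frame of class `ranked_hits` with columns `rank`,
#'   `experiment`, `molecule`, `score`, `q_up_d_dn`, `q_dn_d_up`,
#'   `q_up_d_up`, `q_dn_d_dn`; attribute `cell_type` carries the query's
#'   label.
#' @export
rank_drugs <- function(q, bank, scorer = c("overlap", "ks"),
                       mode = c("reverse", "mimic"), top_n = 50,
                       unique_molecules = FALSE) {
  scorer <- match.arg(scorer); mode <- match.arg(mode)
  if (!length(bank$experiments)) stop("drug bank is empty")
  ids <- names(bank$experiments)
  det <- t(vapply(bank$experiments, overlap_detail, numeric(4),
                  q = q))
  score <- if (scorer == "overlap") {
    vapply(bank$experiments, overlap_score, numeric(1), q = q, mode = mode)
  } else {
    vapply(bank$experiments, function(d)
      ks_connectivity(q, experiment_ranked_list(d, bank$gene_universe)),
      numeric(1))
  }
  asc <- scorer == "ks" && mode == "reverse"
  ord <- order(if (asc) score else -score, ids)
  res <- data.frame(
    rank = seq_along(ord),
    experiment = ids[ord],
    molecule = vapply(bank$experiments[ord], function(e) e$molecule,
                      character(1)),
    score = score[ord],
    det[ord, , drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL)
  if (unique_molecules) {
    res <- res[!duplicated(res$molecule), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
  }
  res <- utils::head(res, top_n)
  attr(res, "cell_type") <- q$cell_type
  class(res) <- c("ranked_hits", class(res))
  res
}
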