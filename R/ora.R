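#' Map annotated DMRs to their unique gene list
#'
#' Returns the deduplicated gene ids of an annotated DMR set, including the
#' nearest genes assigned to distal intergenic DMRs; NA assignments (empty
#' gene universe) are dropped.
#'
#' @param annotated output of [annotate_dmrs()].
#' @return character vector of unique gene ids.
#' @export
map_dmrs_to_genes <- function(annotated) {
  unique(annotated$gene_id[!is.na(annotated$gene_id)])
}

#' Gene-set over-representation test
#'
#' One-sided hypergeometric test per gene set: with a universe of `N` genes of
#' which `K` belong to the set, and a query of `n` genes with `k` hits,
#' `p = P(X >= k)`. BH adjustment runs across all sets; `q <= fdr_report`
#' flags the reported tier. Query genes outside the universe are dropped with
#' a warning.
#'
#' @param query_genes character vector of query gene ids.
#' @param universe_genes character vector defining the background universe.
#' @param gene_sets named list of gene-id vectors (see [load_gene_sets()]).
#' @param fdr_report BH threshold for the `reported` flag (default 0.1).
#' @return data.frame: set, k, n, K, N, p, q, reported, hits
#'   (comma-separated), sorted by p.
#' @export
ora_test <- function(query_genes, universe_genes, gene_sets,
                     fdr_report = 0.1) {
  universe <- unique(universe_genes)
  if (!length(universe)) stop_param("empty universe")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    hits <- intersect(query, set)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N, p = p,
               hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$reported <- out$q <= fdr_report
  out[order(out$p, out$set),
      c("set", "k", "n", "K", "N", "p", "q", "reported", "hits")]
}
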