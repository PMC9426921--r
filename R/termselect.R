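#' GREAT-style enrichment of one ontology term
#'
#' Two tests against the query's informative elements. The region-based
#' binomial asks whether more query elements fall inside the term's merged
#' regulatory domain than expected from the domain's non-gap base fraction
#' `p_pi`. The gene-based hypergeometric asks whether, among the genes whose
#' domain is hit by the query, those annotated to the term are
#' over-represented (universe = all genes carrying at least one propagated
#' annotation).
#'
#' @param query_elems `GRanges` of informative query elements.
#' @param term_id Term identifier (must already pass the gene-count filter).
#' @param refs A `tf_reference`.
#' @param genes_hit Optional pre-computed character vector of universe genes
#'   whose regulatory domain overlaps the query (recomputed when `NULL`).
#' @return One-row data.frame: `term_id`, `binom_p`, `hyper_p`, their
#'   natural-log versions, `n_genes_term`, `n_genes_hit`, `region_hits`,
#'   `p_term`.
#' @export
great_term_test <- function(query_elems, term_id, refs, genes_hit = NULL) {
  annot <- refs$annot
  if (is.null(annot$term_genes[[term_id]])) {
    stop("unknown term: ", term_id)
  }
  if (is.null(genes_hit)) genes_hit <- query_hit_genes(query_elems, refs)
  dom <- term_domain(term_id, refs$regdom, annot)
  region_hits <- sum(IRanges::overlapsAny(query_elems, dom,
                                          ignore.strand = TRUE))
  denom <- merged_length(refs$nongap)
  if (denom == 0) stop("non-gap region set is empty")
  p_term <- merged_length(GenomicRanges::intersect(
    dom, granges_only(refs$nongap), ignore.strand = TRUE)) / denom
  lbin <- binomial_tail(region_hits, length(query_elems), p_term,
                        log.p = TRUE)
  term_g <- annot$term_genes[[term_id]]
  k_gene <- length(intersect(term_g, genes_hit))
  lhyp <- hypergeometric_tail(k_gene, length(genes_hit), length(term_g),
                              length(annot$genes), log.p = TRUE)
  data.frame(
    term_id = term_id,
    binom_p = max(exp(lbin), .Machine$double.xmin),
    hyper_p = max(exp(lhyp), .Machine$double.xmin),
    log_binom_p = lbin,
    log_hyper_p = lhyp,
    n_genes_term = length(term_g),
    n_genes_hit = k_gene,
    region_hits = region_hits,
    p_term = p_term,
    stringsAsFactors = FALSE
  )
}

# universe genes whose regulatory domain overlaps >= 1 query element
query_hit_genes <- function(query_elems, refs) {
  regdom <- refs$regdom
  keep <- S4Vectors::mcols(regdom)$name %in% refs$annot$genes
  regdom <- regdom[keep]
  hit <- IRanges::overlapsAny(regdom, query_elems, ignore.strand = TRUE)
  S4Vectors::mcols(regdom)$name[hit]
}

#' Select the top enriched ontology terms for a query
#'
#' The strata-defining step: query elements are first restricted to those
#' overlapping at least one binding site of any TF in the library (the
#' informative elements), candidate terms are filtered to those annotating
#' between `gene_min` and `gene_max` genes after propagation, every
#' surviving term is scored with [great_term_test()], and terms are ordered
#' by ascending region-binomial p-value (ties: ascending gene-hypergeometric
#' p-value, then term id). The leading `k_terms` terms are returned; the
#' ordering does not depend on `k_terms`, so smaller selections are prefixes
#' of larger ones.
#'
#' @param query `GRanges` of accessible regions.
#' @param tfbs_lib A `tfbs_library`.
#' @param refs A `tf_reference`.
#' @param k_terms Number of terms to keep (default 100).
#' @param gene_min,gene_max Propagated gene-count bounds for candidate terms.
#' @return A `term_selection`: data.frame of per-term statistics in rank
#'   order, with the informative query elements attached as attribute
#'   `query_elems`.
#' @export
select_top_terms <- function(query, tfbs_lib, refs, k_terms = 100,
                             gene_min = 2, gene_max = 500) {
  stopifnot(k_terms >= 1, gene_min >= 1, gene_max >= gene_min)
  all_sites <- suppressWarnings(do.call(
    c, lapply(unname(tfbs_lib), granges_only)))
  query_elems <- select_overlapping_elements(query, all_sites)
  if (length(query_elems) == 0L) {
    stop("no informative regions: no query element overlaps any TFBS")
  }
  cand <- names(refs$annot$n_genes)[refs$annot$n_genes >= gene_min &
                                    refs$annot$n_genes <= gene_max]
  if (!length(cand)) stop("no ontology term passes the gene-count filter")
  genes_hit <- query_hit_genes(query_elems, refs)
  rows <- lapply(cand, great_term_test, query_elems = query_elems,
                 refs = refs, genes_hit = genes_hit)
  tab <- do.call(rbind, rows)
  o <- order(tab$log_binom_p, tab$log_hyper_p, tab$term_id,
             method = "radix")
  tab <- tab[o[seq_len(min(k_terms, nrow(tab)))], , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, query_elems = query_elems, class = c("term_selection",
                                                      "data.frame"))
}
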