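#' Abundance-only binomial-fold TF ranking
#'
#' The function-agnostic comparator: for each TF, count the binding sites
#' intersecting the query, compute the binomial tail of that count at the
#' genomic background rate (fraction of the genome covered by the query),
#' and rank TFs by descending fold enrichment `(m_i / M_i) / c`. No
#' ontology information enters; a TF with many raw sites in the query leads
#' regardless of where those sites sit functionally.
#'
#' @param query `GRanges` of accessible regions.
#' @param tfbs_lib A `tfbs_library`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param nongap Optional `GRanges`; when supplied, the background fraction
#'   uses non-gap bases instead of total chromosome length.
#' @return Data.frame ordered by descending fold (ties: ascending p-value,
#'   then TF name): `rank`, `tf`, `total_sites`, `sites_in_query`,
#'   `coverage_fraction`, `binom_p`, `fold`.
#' @export
abundance_ranking <- function(query, tfbs_lib, chrom_sizes, nongap = NULL) {
  if (length(query) == 0L) stop("empty query region set")
  genome_len <- if (is.null(nongap)) {
    sum(as.numeric(chrom_sizes))
  } else {
    merged_length(nongap)
  }
  cfrac <- merged_length(query) / genome_len
  m_total <- vapply(tfbs_lib, length, integer(1))
  m_query <- vapply(tfbs_lib, function(gr) {
    length(unique(granges_only(select_overlapping_elements(gr, query))))
  }, integer(1))
  p <- binomial_tail(m_query, m_total, cfrac)
  fold <- binomial_fold(m_query, m_total, cfrac)
  tfs <- names(tfbs_lib)
  o <- order(-fold, p, tfs, method = "radix")
  out <- data.frame(
    rank = seq_along(tfs),
    tf = tfs[o],
    total_sites = unname(m_total[o]),
    sites_in_query = unname(m_query[o]),
    coverage_fraction = cfrac,
    binom_p = unname(p[o]),
    fold = unname(fold[o]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
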