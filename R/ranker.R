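#' TF-by-term enrichment matrix
#'
#' For each TF track the elements overlapping the query are counted
#' (`n_i`), and within each selected term's merged regulatory domain the
#' subset of those elements falling inside the domain (`k_ij`). The same
#' counts for the union of all TF tracks give `N_elem` and `K_j`. Two
#' per-cell significance measures follow: a hypergeometric tail
#' (`k_ij` successes among `n_i` draws from `N_elem` with `K_j` marked) and
#' a binomial tail of `k_ij` out of `n_i` at the term's non-gap base
#' fraction. A TF with no sites in the query gets p = 1 everywhere.
#'
#' @param query_elems `GRanges` of informative query elements (attribute of
#'   a `term_selection`), or any query region set.
#' @param tfbs_lib A `tfbs_library`.
#' @param selection A `term_selection` from [select_top_terms()].
#' @param refs A `tf_reference`.
#' @return A `tf_term_matrix`: list with `tfs`, `terms`, count vector `n_i`,
#'   matrices `k` (TF x term), `log_hyper_p`, `log_binom_p`, scalar
#'   `N_elem`, vector `K_j`, and `p_term`.
#' @export
compute_tf_term_matrix <- function(query_elems, tfbs_lib, selection, refs) {
  stopifnot(nrow(selection) >= 1)
  tfs <- names(tfbs_lib)
  terms <- selection$term_id
  # per-TF element sets: distinct coordinates (a region set has no
  # duplicate elements)
  in_query <- lapply(tfbs_lib, function(gr) {
    unique(granges_only(select_overlapping_elements(gr, query_elems)))
  })
  n_i <- vapply(in_query, length, integer(1))
  # element-level union: distinct intervals, not base-merged, so that each
  # TF's in-query elements stay a subset of the union set
  union_sites <- unique(sort_intervals(suppressWarnings(do.call(
    c, lapply(unname(in_query), granges_only)))))
  n_elem <- length(union_sites)
  doms <- lapply(terms, term_domain, regdom = refs$regdom,
                 annot = refs$annot)
  # every TF element is an element of the union set, so domain overlap is
  # resolved once on the union and looked up per TF
  idx <- lapply(in_query, function(gr) {
    S4Vectors::match(gr, union_sites)
  })
  k <- matrix(0L, nrow = length(tfs), ncol = length(terms),
              dimnames = list(tfs, terms))
  K_j <- integer(length(terms))
  for (j in seq_along(terms)) {
    in_dom <- IRanges::overlapsAny(union_sites, doms[[j]],
                                   ignore.strand = TRUE)
    K_j[j] <- sum(in_dom)
    k[, j] <- vapply(idx, function(ii) sum(in_dom[ii]), integer(1))
  }
  log_hyper <- matrix(0, nrow = length(tfs), ncol = length(terms),
                      dimnames = list(tfs, terms))
  log_binom <- log_hyper
  for (j in seq_along(terms)) {
    log_hyper[, j] <- hypergeometric_tail(k[, j], n_i,
                                          K_j[j], n_elem, log.p = TRUE)
    log_binom[, j] <- binomial_tail(k[, j], n_i, selection$p_term[j],
                                    log.p = TRUE)
  }
  structure(
    list(tfs = tfs, terms = terms, n_i = n_i, k = k,
         N_elem = n_elem, K_j = stats::setNames(K_j, terms),
         log_hyper_p = log_hyper, log_binom_p = log_binom,
         p_term = stats::setNames(selection$p_term, terms)),
    class = "tf_term_matrix"
  )
}

#' Rank TFs within each term
#'
#' Within every term, TFs are ordered by ascending hypergeometric p-value,
#' ties by ascending binomial p-value, remaining ties alphabetically by TF
#' name, and assigned ranks 1..N. The result is invariant to the input
#' order of TFs.
#'
#' @param mat A `tf_term_matrix`.
#' @return Integer matrix (TF x term) of ranks; each column is a
#'   permutation of 1..N.
#' @export
rank_within_terms <- function(mat) {
  tfs <- mat$tfs
  ranks <- matrix(0L, nrow = length(tfs), ncol = length(mat$terms),
                  dimnames = list(tfs, mat$terms))
  for (j in seq_along(mat$terms)) {
    o <- order(mat$log_hyper_p[, j], mat$log_binom_p[, j], tfs,
               method = "radix")
    ranks[o, j] <- seq_along(tfs)
  }
  ranks
}

#' Per-term significance mask
#'
#' A TF is significant for a term when it passes the adaptive leap
#' threshold for both the hypergeometric and the binomial column of that
#' term (logical AND of the two kept sets). A TF with no site at all
#' inside the term's domain (`k = 0`) is never significant for that term:
#' in a stratum carrying no signal every p-value ties at 1 and the leap
#' tie rule alone would otherwise mark the whole library significant
#' there, letting alphabetically early TFs collect spurious partial
#' scores.
#'
#' @param mat A `tf_term_matrix`.
#' @param top_m Leading p-values inspected by [adaptive_threshold()].
#' @return Logical matrix (TF x term).
#' @export
significance_mask <- function(mat, top_m = 10) {
  sig <- matrix(FALSE, nrow = length(mat$tfs), ncol = length(mat$terms),
                dimnames = list(mat$tfs, mat$terms))
  for (j in seq_along(mat$terms)) {
    hy <- adaptive_threshold(stats::setNames(mat$log_hyper_p[, j],
                                             mat$tfs), top_m)$keep
    bi <- adaptive_threshold(stats::setNames(mat$log_binom_p[, j],
                                             mat$tfs), top_m)$keep
    sig[, j] <- hy & bi
  }
  if (!is.null(mat$k)) sig <- sig & (mat$k >= 1)
  sig
}

#' Stratified partial scores and total scores
#'
#' The partial score of TF i in the j-th selected term is
#' `Significant(i, j) / (j * Rank(i, j))`; the TF's total score is the sum
#' over terms. Term position j discounts lower-ranked strata, the in-term
#' rank discounts weaker TFs within a stratum.
#'
#' @param mask Logical significance matrix.
#' @param ranks Integer rank matrix.
#' @return List with matrix `partial` (TF x term) and named vector `score`.
#' @export
partial_scores <- function(mask, ranks) {
  stopifnot(identical(dim(mask), dim(ranks)))
  j_idx <- matrix(rep(seq_len(ncol(ranks)), each = nrow(ranks)),
                  nrow = nrow(ranks))
  partial <- ifelse(mask, 1 / (j_idx * ranks), 0)
  dimnames(partial) <- dimnames(ranks)
  list(partial = partial, score = rowSums(partial))
}

#' Top contributing terms for one TF
#'
#' Terms with a positive partial score for the TF, ordered by descending
#' partial score with ties broken by earlier term position.
#'
#' @param tf TF name.
#' @param partial Partial-score matrix from [partial_scores()].
#' @return Data.frame with `term_id`, `position` (j), `partial_score`.
#' @export
top_contributing_terms <- function(tf, partial) {
  v <- partial[tf, ]
  keep <- which(v > 0)
  o <- keep[order(-v[keep], keep)]
  data.frame(term_id = colnames(partial)[o], position = o,
             partial_score = unname(v[o]), stringsAsFactors = FALSE)
}

#' Closed-loop annotation check
#'
#' Does the term driving a TF's ranking annotate the TF's own gene? The
#' ranking derives a term from the TF's putative downstream targets, so the
#' TF gene itself carrying the same (propagated) annotation is independent
#' support. Returns `NA` when the TF has no gene mapping.
#'
#' @param tf TF name.
#' @param term_id Term identifier.
#' @param annot An `annotation_table`.
#' @param tf_gene_map Named character vector (TF -> gene_id), or `NULL`.
#' @return `TRUE`, `FALSE`, or `NA` (mapping unavailable).
#' @export
closed_loop_check <- function(tf, term_id, annot, tf_gene_map = NULL) {
  if (is.null(tf_gene_map) || is.na(tf_gene_map[tf]) ||
      !tf %in% names(tf_gene_map)) {
    return(NA)
  }
  gene <- unname(tf_gene_map[tf])
  gene %in% annot$term_genes[[term_id]]
}
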