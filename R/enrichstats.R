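#' Upper binomial tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, evaluated in log space so that
#' extreme enrichments do not underflow to zero. The returned probability is
#' floored at the smallest positive double.
#'
#' @param k Observed success count, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p Per-trial success probability.
#' @param log.p Return the natural-log probability instead.
#' @return A p-value in `(0, 1]`, or its natural log.
#' @export
binomial_tail <- function(k, n, p, log.p = FALSE) {
  if (any(k < 0) || any(k > n) || any(n < 0)) {
    stop("binomial_tail requires 0 <= k <= n")
  }
  if (any(p < 0) || any(p > 1)) stop("binomial_tail requires 0 <= p <= 1")
  lp <- stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE)
  lp <- pmin(lp, 0)
  if (log.p) lp else pmax(exp(lp), .Machine$double.xmin)
}

#' Upper hypergeometric tail probability
#'
#' `P(X >= k)` when drawing `n` elements without replacement from a
#' population of `N` containing `K` successes. Log-space evaluation; floored
#' at the smallest positive double.
#'
#' @param k Observed successes among the draws.
#' @param n Number of draws.
#' @param K Successes in the population.
#' @param N Population size.
#' @param log.p Return the natural-log probability instead.
#' @return A p-value in `(0, 1]`, or its natural log.
#' @export
hypergeometric_tail <- function(k, n, K, N, log.p = FALSE) {
  if (any(k < 0) || any(n < 0) || any(K < 0) ||
      any(n > N) || any(K > N) || any(k > pmin(n, K))) {
    stop("hypergeometric_tail requires 0 <= k <= min(n, K) and n, K <= N")
  }
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  lp <- pmin(lp, 0)
  if (log.p) lp else pmax(exp(lp), .Machine$double.xmin)
}

#' Adaptive leap threshold over a set of p-values
#'
#' Implements the per-term TF significance cutoff: sort the p-values
#' ascending, inspect the top `top_m`, compute the gaps between adjacent
#' negative log p-values `d_k = -log(p_k / p_{k+1})`, and place the
#' threshold at the p-value before the largest gap (smallest index on ties,
#' i.e. the most stringent choice). Every TF in the full input with
#' `p <= p_m` is kept, not just those inspected. With a single finite
#' p-value a leap is undefined and that lone TF is kept.
#'
#' All arithmetic is on natural-log p-values so underflown ratios never
#' collapse.
#'
#' @param log_p Named numeric vector of natural-log p-values (one per TF).
#' @param top_m How many leading p-values to inspect for the leap.
#' @return A list with `m` (leap index), `threshold_log_p`, and `keep`, a
#'   named logical vector aligned with `log_p`.
#' @export
adaptive_threshold <- function(log_p, top_m = 10) {
  stopifnot(top_m >= 1)
  finite <- is.finite(log_p)
  if (!any(finite)) stop("adaptive_threshold: no finite p-values")
  o <- order(log_p, names(log_p), method = "radix")
  o <- o[finite[o]]
  m_used <- min(top_m, length(o))
  top <- log_p[o[seq_len(m_used)]]
  if (m_used == 1L) {
    m <- 1L
  } else {
    d <- diff(top)  # = -log(p_k / p_{k+1}) on the log scale
    m <- unname(which.max(d))  # first index on ties: most stringent
  }
  thr <- unname(top[m])
  list(m = m, threshold_log_p = thr,
       keep = stats::setNames(is.finite(log_p) & log_p <= thr,
                              names(log_p)))
}

#' Binomial fold enrichment
#'
#' Observed in-query fraction of a TF's sites relative to the background
#' fraction of the genome covered by the query. The statistic behind the
#' abundance-only baseline ranking.
#'
#' @param k Sites intersecting the query.
#' @param n Total sites for the TF.
#' @param background_fraction Fraction of the genome covered by the query.
#' @return Non-negative fold enrichment.
#' @export
binomial_fold <- function(k, n, background_fraction) {
  if (any(n <= 0)) stop("binomial_fold requires n > 0")
  if (any(background_fraction <= 0)) {
    stop("binomial_fold requires background_fraction > 0")
  }
  (k / n) / background_fraction
}
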