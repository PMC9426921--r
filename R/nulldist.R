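#' Exact null distribution of the stratified score
#'
#' Under the null, every ordering of the N TFs within each term is equally
#' likely, so a TF's score is a sum over terms of independent draws: with
#' probability 1/N it lands on rank r of term j and collects `1/(j*r)` if
#' position r scores there, otherwise 0. The distribution of the total is
#' built level by level: `S_0 = {(0, 1)}`; level j+1 combines every
#' cumulative score with every summand of term j+1, aggregating equal
#' scores and adding configuration counts. After the last level,
#' `P(score >= x)` is the aggregated count at or above `x` divided by
#' `N^K`.
#'
#' Scores are carried as exact integer numerators over the least common
#' multiple of all summand denominators `j*r` whenever that stays within
#' exact double-integer range; otherwise (or when the state space exceeds
#' `max_states`) scores are rounded to 12 decimal digits for merging, which
#' is flagged in the result.
#'
#' @param positions List of length K; element j holds the integer rank
#'   positions of term j that score (may be empty).
#' @param n_tf Number of TFs being permuted.
#' @param max_states Cap on distinct cumulative scores before switching to
#'   rounded merging.
#' @return A `score_distribution`: list with `levels` (per level j, a list
#'   of `score`, `count` vectors on the score scale), `mode`
#'   (`"exact"`/`"rounded"`), `denom`, `n_tf`, `K`, `total` (= `n_tf^K`),
#'   and the native final-level representation used by
#'   [tail_probability()].
#' @export
null_score_distribution <- function(positions, n_tf, max_states = 2e6) {
  stopifnot(n_tf >= 1)
  K <- length(positions)
  positions <- lapply(positions, function(p) sort(as.numeric(p)))
  for (j in seq_len(K)) {
    p <- positions[[j]]
    if (length(p) > n_tf || (length(p) && (any(p < 1) || any(p > n_tf) ||
                                           anyDuplicated(p)))) {
      stop("scoring positions at level ", j, " invalid for n_tf = ", n_tf)
    }
  }
  dens <- unlist(lapply(seq_len(K), function(j) j * positions[[j]]),
                 use.names = FALSE)
  L <- lcm_capped(unique(dens), cap = 2^44)
  exact <- !is.na(L)
  res <- dp_run(positions, n_tf, exact, L, max_states)
  if (is.null(res)) {  # state cap hit in exact mode: redo with rounding
    warning("null-score DP state cap reached; merging scores rounded ",
            "to 12 digits")
    exact <- FALSE
    res <- dp_run(positions, n_tf, FALSE, NA_real_, max_states)
  }
  structure(
    list(levels = res$levels, mode = if (exact) "exact" else "rounded",
         denom = if (exact) L else NA_real_, n_tf = n_tf, K = K,
         total = n_tf^K, final_native = res$final),
    class = "score_distribution"
  )
}

# least common multiple of integer-valued doubles, NA when exceeding cap
lcm_capped <- function(x, cap) {
  if (!length(x)) return(1)
  gcd2 <- function(a, b) {
    while (b > 0) { t <- b; b <- a %% b; a <- t }
    a
  }
  L <- 1
  for (v in x) {
    L <- L / gcd2(L, v) * v
    if (L > cap) return(NA_real_)
  }
  L
}

# one full DP pass; returns NULL if the exact-mode state cap is exceeded
dp_run <- function(positions, n_tf, exact, L, max_states) {
  s <- 0
  cnt <- 1
  levels <- vector("list", length(positions))
  for (j in seq_along(positions)) {
    p <- positions[[j]]
    tv <- if (exact) L / (j * p) else 1 / (j * p)
    tm <- rep(1, length(p))
    zero_mult <- n_tf - length(p)
    if (zero_mult > 0) {
      tv <- c(tv, 0)
      tm <- c(tm, zero_mult)
    }
    ns <- rep(s, times = length(tv)) + rep(tv, each = length(s))
    nc <- rep(cnt, times = length(tv)) * rep(tm, each = length(s))
    if (!exact) ns <- round(ns, 12)
    agg <- data.table::data.table(s = ns, n = nc)
    agg <- agg[, list(n = sum(n)), by = "s"]
    data.table::setorderv(agg, "s")
    s <- agg$s
    cnt <- agg$n
    if (exact && length(s) > max_states) return(NULL)
    levels[[j]] <- list(score = if (exact) s / L else s, count = cnt)
  }
  list(levels = levels, final = list(s = s, n = cnt))
}

#' Tail probability of an observed score under the null
#'
#' `P(null score >= observed)`, where the observed score is specified by
#' the (term position, in-term rank) pairs at which the TF scores, so that
#' in exact mode the comparison is performed on integer numerators with no
#' floating-point ambiguity.
#'
#' @param dist A `score_distribution`.
#' @param j Integer vector of term positions where the TF is significant.
#' @param r Integer vector of the TF's (compacted) ranks at those terms.
#' @return A p-value in `(0, 1]`.
#' @export
tail_probability <- function(dist, j, r) {
  stopifnot(length(j) == length(r))
  s <- dist$final_native$s
  n <- dist$final_native$n
  if (dist$mode == "exact") {
    obs <- if (length(j)) sum(dist$denom / (j * r)) else 0
    keep <- s >= obs
  } else {
    obs <- if (length(j)) round(sum(1 / (j * r)), 12) else 0
    keep <- s >= obs - 1e-9
  }
  sum(n[keep]) / dist$total
}

# scoring positions per term and the focal TF's own (j, r) pairs, after
# removing a set of TFs and compacting the remaining ranks
compacted_positions <- function(mask, ranks, removed, tf = NULL) {
  keep_tfs <- setdiff(rownames(ranks), removed)
  K <- ncol(ranks)
  positions <- vector("list", K)
  obs_j <- integer(0)
  obs_r <- integer(0)
  for (jj in seq_len(K)) {
    r_rem <- ranks[removed, jj]
    r_keep <- ranks[keep_tfs, jj]
    comp <- r_keep - vapply(r_keep, function(x) sum(r_rem < x), numeric(1))
    sig <- mask[keep_tfs, jj]
    positions[[jj]] <- sort(comp[sig])
    if (!is.null(tf) && mask[tf, jj]) {
      obs_j <- c(obs_j, jj)
      obs_r <- c(obs_r, comp[[match(tf, keep_tfs)]])
    }
  }
  list(positions = positions, n_tf = length(keep_tfs),
       obs_j = obs_j, obs_r = obs_r)
}

#' Marginal score p-value of one TF
#'
#' Significance of the TF's observed score against the full-library null
#' (no conditioning).
#'
#' @param mask Logical significance matrix (TF x term).
#' @param ranks Integer rank matrix.
#' @param tf TF name.
#' @return A p-value in `(0, 1]`.
#' @export
marginal_pvalue <- function(mask, ranks, tf) {
  cp <- compacted_positions(mask, ranks, removed = character(0), tf = tf)
  dist <- null_score_distribution(cp$positions, cp$n_tf)
  tail_probability(dist, cp$obs_j, cp$obs_r)
}

#' Conditional p-values down the score ranking
#'
#' TF scores are not independent: a high-ranked TF occupies strong rank
#' positions that are then unavailable to the rest. The i-th ranked TF is
#' therefore tested conditionally: the i-1 higher-scoring TFs are deleted
#' from every term's ordering, remaining ranks are compacted preserving
#' order, retained significance flags define the scoring positions, the
#' focal TF's score is recomputed under the compacted ranks, and the null
#' is rebuilt with N - (i-1) TFs. For i = 1 nothing is removed, so the
#' conditional p-value equals the marginal one exactly.
#'
#' @param mask Logical significance matrix (TF x term).
#' @param ranks Integer rank matrix.
#' @param tf_order Character vector of TFs in descending score order.
#' @return Named numeric vector of conditional p-values along `tf_order`.
#' @export
conditional_pvalues <- function(mask, ranks, tf_order) {
  out <- stats::setNames(numeric(length(tf_order)), tf_order)
  for (i in seq_along(tf_order)) {
    cp <- compacted_positions(mask, ranks,
                              removed = tf_order[seq_len(i - 1)],
                              tf = tf_order[i])
    dist <- null_score_distribution(cp$positions, cp$n_tf)
    out[i] <- tail_probability(dist, cp$obs_j, cp$obs_r)
  }
  out
}
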