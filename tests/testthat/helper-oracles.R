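# Shorthand constructors and independent brute-force oracles used across
# the suite. Oracles deliberately avoid the code paths they check.

# 0-based half-open intervals on a single default chromosome
gset <- function(start, end, chrom = "chr1", name = NULL, score = NULL,
                 chrom_sizes = NULL) {
  interval_set(rep(chrom, length.out = length(start)), start, end,
               name = name, score = score, chrom_sizes = chrom_sizes)
}

# plain data.frame view in 0-based half-open coordinates
as_bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr))
}

# random interval set on a toy genome
random_gset <- function(n, glen = 10000, max_w = 300, chrom = "chr1",
                        score = FALSE) {
  s <- sample.int(glen - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  gset(s, pmin(s + w, glen), chrom = chrom,
       score = if (score) sample(1:50, n, replace = TRUE))
}

# per-base occupancy over a toy genome (bit-vector oracle)
base_vector <- function(gr, glen) {
  v <- logical(glen)
  df <- as_bed_df(gr)
  for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}

# all-pairs O(n*m) element overlap oracle
overlap_oracle <- function(elements, selector) {
  ed <- as_bed_df(elements)
  sd <- as_bed_df(selector)
  keep <- vapply(seq_len(nrow(ed)), function(i) {
    any(sd$chrom == ed$chrom[i] & sd$start < ed$end[i] &
          sd$end > ed$start[i])
  }, logical(1))
  elements[keep]
}

# direct log-space summation of the upper binomial tail
binom_tail_oracle <- function(k, n, p) {
  if (k == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  x <- k:n
  sum(exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)))
}

# upper hypergeometric tail by summing the exact pmf with choose()
hyper_tail_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  x <- k:min(n, K)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# hypergeometric tail by enumerating every n-subset of 1..N (tiny N only)
hyper_tail_enum <- function(k, n, K, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # successes are elements 1..K
  mean(hits >= k)
}

# breadth-first ancestor closure, independent of the package's DFS
bfs_ancestors <- function(term, edges) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    parents <- unique(edges$parent[edges$child %in% frontier])
    parents <- setdiff(parents, seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  seen
}

# exhaustive null of the stratified score: every rank configuration of the
# focal TF across K terms (n_tf^K rows), score and tail probability
enum_score_null <- function(positions, n_tf) {
  K <- length(positions)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_tf)), K)))
  scores <- numeric(nrow(grid))
  for (j in seq_len(K)) {
    hit <- grid[, j] %in% positions[[j]]
    scores <- scores + ifelse(hit, 1 / (j * grid[, j]), 0)
  }
  scores
}

enum_tail_prob <- function(positions, n_tf, observed, tol = 1e-9) {
  scores <- enum_score_null(positions, n_tf)
  mean(scores >= observed - tol)
}

# random significance-position instance for DP-vs-enumeration checks
random_positions <- function(n_tf, K) {
  lapply(seq_len(K), function(j) {
    s <- sample(0:n_tf, 1)
    if (s == 0) integer(0) else sort(sample.int(n_tf, s))
  })
}

# observed score of a TF from its (term position, rank) pairs
pair_score <- function(j, r) if (length(j)) sum(1 / (j * r)) else 0
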