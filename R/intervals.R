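#' Construct a genomic interval set
#'
#' Builds a `GRanges` from BED-style coordinates: 0-based starts, exclusive
#' ends. This is the container used throughout the package for peaks, binding
#' sites, and regulatory domains. Intervals are validated and returned in the
#' canonical order (chromosome lexicographic, start, end, name).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start offsets.
#' @param end Integer vector, exclusive end offsets (`start < end`).
#' @param name Optional character labels.
#' @param score Optional numeric scores.
#' @param chrom_sizes Optional named vector of chromosome lengths; when given,
#'   every interval must fit inside its chromosome.
#' @return A `GRanges` with optional `name`/`score` metadata columns.
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         chrom_sizes = NULL) {
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(chrom_sizes)) {
      GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
      GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_sizes)
    }
    return(gr)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must exceed start")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- as.numeric(score)
  if (!is.null(chrom_sizes)) gr <- apply_chrom_sizes(gr, chrom_sizes)
  sort_intervals(gr)
}

#' @keywords internal
apply_chrom_sizes <- function(gr, chrom_sizes) {
  bad <- setdiff(GenomeInfoDb::seqlevelsInUse(gr), names(chrom_sizes))
  if (length(bad)) {
    stop("chromosome(s) not in the sizes table: ", paste(bad, collapse = ", "))
  }
  sn <- as.character(GenomeInfoDb::seqnames(gr))
  over <- BiocGenerics::end(gr) > unname(chrom_sizes[sn])
  if (any(over)) {
    stop("interval(s) extend beyond chromosome end on ",
         paste(unique(sn[over]), collapse = ", "))
  }
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_sizes)
  gr
}

#' Canonical deterministic ordering of an interval set
#'
#' Orders by (chromosome lexicographic, start, end, name), so that repeated
#' runs and permuted inputs yield byte-identical downstream reports.
#'
#' @param gr A `GRanges`.
#' @return The same `GRanges`, reordered.
#' @export
sort_intervals <- function(gr) {
  if (length(gr) == 0L) return(gr)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- rep("", length(gr))
  o <- order(as.character(GenomeInfoDb::seqnames(gr)),
             BiocGenerics::start(gr), BiocGenerics::end(gr), nm,
             method = "radix")
  gr[o]
}

#' Number of elements in an interval set
#' @param gr A `GRanges`.
#' @return Integer count of elements (not bases).
#' @export
n_elements <- function(gr) length(gr)

# Fails loudly on "chr1" vs "1" style naming mismatches instead of silently
# reporting zero overlap. Chromosome names are compared as exact strings.
check_chrom_compat <- function(a, b) {
  ca <- unique(as.character(GenomeInfoDb::seqnames(a)))
  cb <- unique(as.character(GenomeInfoDb::seqnames(b)))
  if (length(ca) && length(cb) && !length(intersect(ca, cb))) {
    stop("no shared chromosome names between the two interval sets ",
         "(e.g. ", ca[1], " vs ", cb[1],
         "); check the naming convention")
  }
  invisible(TRUE)
}

#' Select elements overlapping a selector set
#'
#' Returns the elements of `elements` that overlap at least one base of any
#' interval in `selector`. Elements are kept whole (no trimming) and each
#' appears at most once, mirroring element-level overlap selection of BED
#' features.
#'
#' @param elements A `GRanges` whose elements are candidates.
#' @param selector A `GRanges` acting as the filter.
#' @return The overlapping subset of `elements`, in canonical order.
#' @export
select_overlapping_elements <- function(elements, selector) {
  if (length(elements) == 0L || length(selector) == 0L) {
    return(elements[integer(0)])
  }
  check_chrom_compat(elements, selector)
  sort_intervals(IRanges::subsetByOverlaps(elements, selector,
                                           ignore.strand = TRUE))
}

#' Base-level subtraction of interval sets
#'
#' Computes the portions of `a` not covered by `b`, as maximal intervals.
#' This is base-resolution subtraction (bedtools-subtract style), not
#' whole-feature removal; metadata columns are dropped because elements may
#' be split.
#'
#' @param a,b `GRanges` objects.
#' @return A `GRanges` covering exactly the bases of `a` absent from `b`.
#' @export
subtract_portions <- function(a, b) {
  if (length(a) == 0L) return(a)
  if (length(b) == 0L) {
    return(sort_intervals(GenomicRanges::reduce(granges_only(a))))
  }
  res <- GenomicRanges::setdiff(granges_only(a), granges_only(b),
                                ignore.strand = TRUE)
  sort_intervals(res)
}

# strip mcols/strand so set operations behave purely on coordinates
granges_only <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  BiocGenerics::strand(gr) <- "*"
  gr
}

#' Merged base length of an interval set
#'
#' Number of distinct bases covered, counting overlapping bases once.
#'
#' @param gr A `GRanges`.
#' @return Non-negative numeric base count.
#' @export
merged_length <- function(gr) {
  if (length(gr) == 0L) return(0)
  sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(
    granges_only(gr)))))
}

#' Trim elements to a maximum length, preserving midpoints
#'
#' Elements longer than `max_len` are replaced by an interval of exactly
#' `max_len` bases centred on the element midpoint; shorter elements pass
#' through unchanged. With 0-based half-open coordinates the centre is
#' `c = floor((start + end) / 2)` and the result is
#' `[c - floor(max_len/2), c + ceil(max_len/2))`, which is deterministic and
#' length-exact for odd inputs.
#'
#' @param gr A `GRanges`.
#' @param max_len Maximum element length in bases (>= 1).
#' @return A `GRanges` with no element longer than `max_len`.
#' @export
trim_to_midpoint <- function(gr, max_len) {
  stopifnot(max_len >= 1)
  if (length(gr) == 0L) return(gr)
  w <- BiocGenerics::width(gr)
  long <- w > max_len
  if (!any(long)) return(gr)
  s0 <- BiocGenerics::start(gr) - 1  # back to 0-based half-open
  e0 <- BiocGenerics::end(gr)
  ctr <- floor((s0 + e0) / 2)
  new_s0 <- ifelse(long, ctr - floor(max_len / 2), s0)
  new_e0 <- ifelse(long, ctr + ceiling(max_len / 2), e0)
  out <- gr
  IRanges::ranges(out) <- IRanges::IRanges(start = new_s0 + 1, end = new_e0)
  sort_intervals(out)
}

#' Keep the top-scoring fraction of elements
#'
#' Retains the `round(fraction * n)` highest-scoring elements (half-up
#' rounding). Elements tied exactly at the cutoff score are chosen uniformly
#' at random; the choice is reproducible for a fixed `seed`. Used to probe
#' ranking stability under peak-set subsampling.
#'
#' @param gr A `GRanges` with a numeric `score` metadata column.
#' @param fraction Fraction of elements to keep, in (0, 1].
#' @param seed Integer seed controlling the random tie-break.
#' @return The retained elements in canonical order.
#' @export
subsample_by_score <- function(gr, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  sc <- S4Vectors::mcols(gr)$score
  if (is.null(sc) || anyNA(sc)) {
    stop("subsample_by_score requires a complete numeric score column")
  }
  n <- length(gr)
  keep_n <- floor(fraction * n + 0.5)  # half-up, unlike round()'s banker rule
  if (keep_n >= n) return(gr)
  if (keep_n == 0L) return(gr[integer(0)])
  cutoff <- sort(sc, decreasing = TRUE)[keep_n]
  above <- which(sc > cutoff)
  at <- which(sc == cutoff)
  need <- keep_n - length(above)
  picked <- if (need >= length(at)) {
    at
  } else {
    withr::with_seed(seed, sample(at, need))
  }
  sort_intervals(gr[sort(c(above, picked))])
}
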