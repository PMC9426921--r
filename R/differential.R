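#' Differentially accessible regions between two samples
#'
#' Base-level subtraction: the portions of `a` not covered by `b`. With
#' `whole_feature = TRUE`, instead drops every element of `a` that overlaps
#' `b` at all and keeps the rest intact.
#'
#' @param a,b `GRanges` of accessible regions on the same assembly.
#' @param whole_feature Remove whole overlapping elements instead of
#'   subtracting covered bases.
#' @return A `GRanges` sharing no base (or no element) with `b`.
#' @export
differential_regions <- function(a, b, whole_feature = FALSE) {
  if (length(a) && length(b)) check_chrom_compat(a, b)
  if (whole_feature) {
    hit <- IRanges::overlapsAny(a, b, ignore.strand = TRUE)
    return(a[!hit])
  }
  subtract_portions(a, b)
}

#' Combine replicate region sets for a contrast side
#'
#' Supports multi-replicate contrasts of the form
#' `(intersection of group 1) minus (union of group 2)`: bases present in
#' every replicate of the first group and in no replicate of the second.
#'
#' @param intersect_sets List of `GRanges`; their base-level intersection
#'   forms the positive side (a single set passes through).
#' @param union_sets Optional list of `GRanges`; the base-level union is
#'   subtracted.
#' @return A `GRanges`.
#' @export
combine_region_sets <- function(intersect_sets, union_sets = NULL) {
  stopifnot(length(intersect_sets) >= 1)
  pos <- Reduce(function(x, y) {
    GenomicRanges::intersect(granges_only(x), granges_only(y),
                             ignore.strand = TRUE)
  }, intersect_sets)
  if (is.null(union_sets) || !length(union_sets)) {
    return(sort_intervals(GenomicRanges::reduce(granges_only(pos))))
  }
  neg <- GenomicRanges::reduce(suppressWarnings(do.call(
    c, lapply(union_sets, granges_only))))
  subtract_portions(pos, neg)
}

#' Differential TF ranking in both directions
#'
#' Runs the full single-sample ranking on the regions accessible in `a`
#' but not `b` (direction `A_minus_B`) and vice versa. An empty
#' differential set in a direction yields a `NULL` ranking for that
#' direction with a message, not an error.
#'
#' @param a,b `GRanges` of accessible regions.
#' @param tfbs_lib A `tfbs_library`.
#' @param refs A `tf_reference`.
#' @param whole_feature Passed to [differential_regions()].
#' @param ... Passed to [rank_tfs()].
#' @return A `differential_result`: list of two elements `A_minus_B` and
#'   `B_minus_A`, each a list with `regions` and `ranking`.
#' @export
run_differential <- function(a, b, tfbs_lib, refs, whole_feature = FALSE,
                             ...) {
  one_direction <- function(x, y, label) {
    regions <- differential_regions(x, y, whole_feature = whole_feature)
    if (length(regions) == 0L) {
      message("no differential regions in direction ", label)
      return(list(regions = regions, ranking = NULL))
    }
    list(regions = regions,
         ranking = rank_tfs(regions, tfbs_lib, refs, ...))
  }
  structure(
    list(A_minus_B = one_direction(a, b, "A_minus_B"),
         B_minus_A = one_direction(b, a, "B_minus_A")),
    class = "differential_result"
  )
}
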