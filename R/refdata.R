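#' Build basal-plus-extension gene regulatory domains
#'
#' Assigns each gene a putative cis-regulatory territory following the
#' GREAT association rule. The basal domain is strand-aware:
#' `[tss - basal_up, tss + basal_down)` for `+` genes and the mirror image
#' for `-` genes. Each flank is then extended away from the basal domain by
#' up to `max_extension` bases, stopping early at the nearest neighbouring
#' gene's basal domain boundary (regardless of the neighbour's strand). A
#' gene always retains its own basal domain even when a neighbour's basal
#' domain overlaps it. Domains are clipped to chromosome bounds.
#'
#' @param genes Data.frame from [read_gene_models()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param basal_up Bases upstream of the TSS in the basal domain.
#' @param basal_down Bases downstream of the TSS in the basal domain.
#' @param max_extension Maximum extension beyond the basal domain, per flank.
#' @return A `GRanges` with one interval per gene and a `gene_id` column.
#' @export
build_regulatory_domains <- function(genes, chrom_sizes,
                                     basal_up = 5000, basal_down = 1000,
                                     max_extension = 1e6) {
  stopifnot(basal_up >= 0, basal_down >= 0, max_extension >= 0)
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(missing_chr)) {
    stop("gene chromosome(s) absent from sizes table: ",
         paste(missing_chr, collapse = ", "))
  }
  if (any(genes$tss < 0 | genes$tss >= unname(chrom_sizes[genes$chrom]))) {
    stop("gene TSS outside chromosome bounds")
  }
  if (basal_up + basal_down < 1) stop("basal domain must span >= 1 base")
  plus <- genes$strand == "+"
  # 0-based half-open basal domain, mirrored for minus-strand genes
  basal_s <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_e <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  clen <- unname(chrom_sizes[genes$chrom])
  basal_s <- pmax(basal_s, 0)
  basal_e <- pmin(basal_e, clen)

  dom_s <- numeric(nrow(genes))
  dom_e <- numeric(nrow(genes))
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    idx <- idx[order(genes$tss[idx])]
    bs <- basal_s[idx]; be <- basal_e[idx]
    n <- length(idx)
    left_lim <- if (n > 1) c(0, cummax(be)[-n]) else 0
    right_lim <- if (n > 1) {
      rev(c(chrom_sizes[[chr]], cummin(rev(bs))[-n]))
    } else {
      chrom_sizes[[chr]]
    }
    ext_s <- pmax(bs - max_extension, left_lim, 0)
    ext_e <- pmin(be + max_extension, right_lim, chrom_sizes[[chr]])
    # the gene's own basal domain is always retained
    dom_s[idx] <- pmin(ext_s, bs)
    dom_e[idx] <- pmax(ext_e, be)
  }
  interval_set(genes$chrom, dom_s, dom_e, name = genes$gene_id,
               chrom_sizes = chrom_sizes)
}

#' Propagate gene annotations up an ontology
#'
#' Computes the transitive closure of gene-to-term annotations over `is_a`
#' edges: a gene annotated to a term is annotated to every ancestor of that
#' term. The edge set must be acyclic; a detected cycle is reported with a
#' witness path.
#'
#' @param annotations Data.frame with `gene_id`, `term_id` (raw relation).
#' @param edges Data.frame with `child`, `parent` term ids; may be empty.
#' @param term_names Optional named character vector of display names.
#' @return An `annotation_table`: list with the propagated `annotations`
#'   data.frame, per-term gene-id list `term_genes`, per-term gene counts
#'   `n_genes`, and the gene universe `genes` (every gene with at least one
#'   annotation).
#' @export
propagate_annotations <- function(annotations, edges, term_names = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  anc <- ontology_ancestors(edges)
  # map each annotated term to itself plus all ancestors
  terms <- unique(annotations$term_id)
  closure <- lapply(terms, function(t) unique(c(t, anc[[t]])))
  names(closure) <- terms
  reps <- lengths(closure[annotations$term_id])
  prop <- data.frame(
    gene_id = rep(annotations$gene_id, reps),
    term_id = unlist(closure[annotations$term_id], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  prop <- unique(prop)
  prop <- prop[order(prop$term_id, prop$gene_id), , drop = FALSE]
  rownames(prop) <- NULL
  term_genes <- split(prop$gene_id, prop$term_id)
  structure(
    list(
      annotations = prop,
      term_genes = term_genes,
      n_genes = vapply(term_genes, length, integer(1)),
      genes = sort(unique(prop$gene_id)),
      term_names = term_names
    ),
    class = "annotation_table"
  )
}

# memoized DFS ancestor closure with cycle detection; returns a named list
# term -> character vector of strict ancestors
ontology_ancestors <- function(edges) {
  if (nrow(edges) == 0L) return(stats::setNames(list(), character(0)))
  parents <- split(edges$parent, edges$child)
  memo <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  visit <- function(term, path) {
    st <- state[[term]]
    if (!is.null(st) && st == 1L) {
      cyc <- c(path[which(path == term)[1]:length(path)], term)
      stop("ontology cycle detected: ", paste(cyc, collapse = " -> "))
    }
    if (!is.null(memo[[term]])) return(memo[[term]])
    state[[term]] <- 1L
    ps <- parents[[term]]
    res <- if (is.null(ps)) character(0) else {
      unique(c(ps, unlist(lapply(ps, visit, path = c(path, term)),
                          use.names = FALSE)))
    }
    state[[term]] <- 2L
    memo[[term]] <- res
    res
  }
  all_terms <- unique(c(edges$child, edges$parent))
  out <- lapply(all_terms, visit, path = character(0))
  names(out) <- all_terms
  out
}

#' Non-gap genome regions
#'
#' Full chromosome extents minus any assembly gaps. When no gap track is
#' supplied the whole genome is treated as non-gap.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param gaps Optional `GRanges` of assembly gaps.
#' @return A `GRanges` of non-gap intervals.
#' @export
nongap_regions <- function(chrom_sizes, gaps = NULL) {
  full <- interval_set(names(chrom_sizes), rep(0, length(chrom_sizes)),
                       unname(chrom_sizes), chrom_sizes = chrom_sizes)
  if (is.null(gaps) || length(gaps) == 0L) return(full)
  out <- subtract_portions(full, gaps)
  if (merged_length(out) == 0) stop("gap track covers the entire genome")
  out
}

#' Merged regulatory domain of an ontology term
#'
#' Union of the regulatory domains of every gene annotated (after
#' propagation) to the term.
#'
#' @param term_id Term identifier.
#' @param regdom `GRanges` of per-gene domains (from
#'   [build_regulatory_domains()]).
#' @param annot An `annotation_table`.
#' @return A reduced `GRanges`.
#' @export
term_domain <- function(term_id, regdom, annot) {
  g <- annot$term_genes[[term_id]]
  if (is.null(g)) stop("term has no annotated genes: ", term_id)
  GenomicRanges::reduce(granges_only(
    regdom[S4Vectors::mcols(regdom)$name %in% g]))
}

#' Background probability of a term's regulatory domain
#'
#' The probability of drawing a base annotated with the term when sampling
#' uniformly from non-gap sequence: merged length of the term domain
#' intersected with non-gap bases, divided by the merged non-gap length.
#'
#' @inheritParams term_domain
#' @param nongap `GRanges` of non-gap regions.
#' @return A probability in `[0, 1]`.
#' @export
term_base_probability <- function(term_id, regdom, annot, nongap) {
  denom <- merged_length(nongap)
  if (denom == 0) stop("non-gap region set is empty")
  dom <- term_domain(term_id, regdom, annot)
  num <- merged_length(GenomicRanges::intersect(dom, granges_only(nongap),
                                                ignore.strand = TRUE))
  num / denom
}

#' Load a per-TF binding-site library
#'
#' Reads one BED track per TF. Tracks larger than `per_tf_cap` that carry
#' scores are truncated to the `per_tf_cap` highest-scoring sites, with ties
#' at the cutoff broken deterministically by coordinate so repeated loads
#' are identical. Unscored tracks are kept whole.
#'
#' @param tracks Either a directory containing `<TF>.bed` files or a named
#'   character vector/list of BED paths (names = TF).
#' @param per_tf_cap Maximum number of sites retained per TF.
#' @param chrom_sizes Optional named vector for coordinate validation.
#' @return A `tfbs_library`: named list of `GRanges`, one per TF, in
#'   alphabetical TF order.
#' @export
load_tfbs_library <- function(tracks, per_tf_cap = 5000, chrom_sizes = NULL) {
  if (length(tracks) == 1L && is.character(tracks) &&
      is.null(names(tracks)) && !dir.exists(tracks)) {
    stop("TFBS directory not found: ", tracks)
  }
  if (length(tracks) == 1L && is.character(tracks) && dir.exists(tracks)) {
    paths <- list.files(tracks, pattern = "\\.bed$", full.names = TRUE)
    if (!length(paths)) stop("no .bed tracks found in ", tracks)
    names(paths) <- sub("\\.bed$", "", basename(paths))
    tracks <- paths
  }
  tracks <- unlist(tracks)
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    stop("TFBS tracks must be named by TF")
  }
  tracks <- tracks[order(names(tracks))]
  lib <- lapply(names(tracks), function(tf) {
    gr <- tryCatch(read_bed(tracks[[tf]], chrom_sizes = chrom_sizes),
                   error = function(e) {
                     stop("failed to read TFBS track for TF '", tf, "': ",
                          conditionMessage(e))
                   })
    cap_tfbs_track(gr, per_tf_cap)
  })
  names(lib) <- names(tracks)
  structure(lib, class = "tfbs_library")
}

# keep the per_tf_cap best-scoring sites; coordinate order breaks score ties
cap_tfbs_track <- function(gr, per_tf_cap) {
  sc <- S4Vectors::mcols(gr)$score
  if (length(gr) <= per_tf_cap || is.null(sc) || anyNA(sc)) return(gr)
  o <- order(-sc, as.character(GenomeInfoDb::seqnames(gr)),
             BiocGenerics::start(gr), BiocGenerics::end(gr),
             method = "radix")
  sort_intervals(gr[o[seq_len(per_tf_cap)]])
}

#' Bundle the reference model for a run
#'
#' Convenience constructor gathering everything the enrichment needs:
#' per-gene regulatory domains, propagated annotations, non-gap regions and
#' chromosome sizes.
#'
#' @param genes Gene models data.frame.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param annotations Raw gene-to-term annotation data.frame.
#' @param edges Ontology `is_a` edge data.frame.
#' @param gaps Optional assembly-gap `GRanges`.
#' @param tf_gene_map Optional named character vector (TF -> gene_id).
#' @param basal_up,basal_down,max_extension Regulatory-domain parameters,
#'   see [build_regulatory_domains()].
#' @return A `tf_reference` list.
#' @export
reference_set <- function(genes, chrom_sizes, annotations, edges,
                          gaps = NULL, tf_gene_map = NULL,
                          basal_up = 5000, basal_down = 1000,
                          max_extension = 1e6) {
  regdom <- build_regulatory_domains(genes, chrom_sizes,
                                     basal_up = basal_up,
                                     basal_down = basal_down,
                                     max_extension = max_extension)
  annot <- propagate_annotations(annotations, edges)
  structure(
    list(
      genes = genes,
      chrom_sizes = chrom_sizes,
      regdom = regdom,
      annot = annot,
      nongap = nongap_regions(chrom_sizes, gaps),
      tf_gene_map = tf_gene_map,
      params = list(basal_up = basal_up, basal_down = basal_down,
                    max_extension = max_extension)
    ),
    class = "tf_reference"
  )
}
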