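#' Read a BED3/BED6 file into a genomic interval set
#'
#' Thin wrapper over [rtracklayer::import()] that returns intervals in the
#' package's canonical order. BED is 0-based half-open on disk; the returned
#' `GRanges` follows the usual 1-based convention.
#'
#' @param path Path to a tab-separated BED file.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   validate coordinates.
#' @return A `GRanges`, possibly with `name` and `score` columns.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  BiocGenerics::strand(gr) <- "*"
  keep <- intersect(c("name", "score"), colnames(S4Vectors::mcols(gr)))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
  if (!is.null(chrom_sizes)) gr <- apply_chrom_sizes(gr, chrom_sizes)
  sort_intervals(gr)
}

#' Write a genomic interval set as BED
#'
#' Coordinates round-trip exactly through [read_bed()].
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a two-column chromosome sizes table
#'
#' @param path TSV with columns: chromosome name, length in bases.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome in sizes table")
  if (any(tab$size <= 0)) stop("non-positive chromosome length")
  stats::setNames(tab$size, tab$chrom)
}

#' Read gene models
#'
#' @param path 4-column TSV: gene_id, chrom, strand (+/-), tss (0-based
#'   offset of the canonical transcription start site).
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene_id", "chrom", "strand", "tss"),
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in gene models")
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tab
}

#' Read raw gene-to-term annotations
#'
#' @param path 2-column TSV: gene_id, term_id.
#' @return A data.frame with columns `gene_id`, `term_id`.
#' @export
read_gene_annotations <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("gene_id", "term_id"),
                    colClasses = "character")
}

#' Read ontology is_a edges
#'
#' @param path 2-column TSV: child term id, parent term id.
#' @return A data.frame with columns `child`, `parent`.
#' @export
read_ontology_edges <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("child", "parent"),
                    colClasses = "character")
}

#' Read the optional TF-to-gene mapping
#'
#' Maps a TF track name to the gene encoding the factor, enabling the
#' closed-loop report column (does a driving term annotate the TF's own
#' gene?).
#'
#' @param path 2-column TSV: tf name, gene_id.
#' @return Named character vector (gene_id named by TF).
#' @export
read_tf_gene_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("tf", "gene_id"),
                           colClasses = "character")
  stats::setNames(tab$gene_id, tab$tf)
}
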