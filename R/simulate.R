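#' Specification of a synthetic input bundle
#'
#' Describes a small genome with gene models, a two-level ontology, a
#' binding-site library, and a query peak set in which one TF is *planted*
#' as functionally dominant: a tunable fraction of its in-query sites is
#' concentrated inside the regulatory domains of one ontology term
#' (emulating a TF whose conserved sites cluster in the regulatory domains
#' of functionally coherent target genes). A *decoy* TF has more raw sites
#' in the query than the planted TF but spreads them uniformly across
#' peaks, so sheer-abundance ranking favours the decoy while
#' function-aware ranking favours the planted TF.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bases.
#' @param n_genes Number of genes (evenly spaced TSS with jitter).
#' @param n_leaf_terms,n_root_terms Leaf and root counts of the two-level
#'   ontology (leaves carry the raw annotations).
#' @param genes_per_term Genes annotated to each leaf term.
#' @param n_tfs Number of TF tracks.
#' @param sites_per_tf Binding sites per TF.
#' @param site_len Binding-site length in bases.
#' @param n_peaks Query peaks.
#' @param peak_len Peak length in bases.
#' @param frac_peaks_planted Fraction of peaks placed inside the planted
#'   term's regulatory domain (the functional signal in the query).
#' @param planted_query_frac Fraction of the planted TF's sites placed
#'   inside the query.
#' @param decoy_query_frac Fraction of the decoy TF's sites placed inside
#'   the query; must be at least `planted_query_frac`.
#' @param concentration Fraction of the planted TF's in-query sites placed
#'   inside the planted term's domain; 0 makes the planted TF uniform with
#'   respect to term domains (negative control).
#' @param seed Integer seed; the bundle is byte-identical per seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chrom = 1, chrom_len = 1e6, n_genes = 60,
                         n_leaf_terms = 9, n_root_terms = 3,
                         genes_per_term = 5, n_tfs = 20,
                         sites_per_tf = 300, site_len = 15,
                         n_peaks = 400, peak_len = 300,
                         frac_peaks_planted = 0.3,
                         planted_query_frac = 0.4,
                         decoy_query_frac = 0.7,
                         concentration = 0.8, seed = 7) {
  stopifnot(concentration >= 0, concentration <= 1,
            decoy_query_frac >= planted_query_frac,
            n_leaf_terms * genes_per_term <= n_genes,
            n_tfs >= 3, n_chrom >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic input bundle
#'
#' Writes every file the pipeline reads: `chrom.sizes`, `genes.tsv`,
#' `annotations.tsv`, `ontology.tsv`, `tf_gene_map.tsv`, `query.bed`
#' (with SCORE column), and one `tfbs/<TF>.bed` per TF. Background TF
#' sites are uniform on the genome; the planted TF follows the
#' concentration design; the decoy TF is enriched in the query but uniform
#' with respect to term domains. Placement avoids chromosome edges by one
#' element length so that the planted-signal tests are not entangled with
#' boundary clipping.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created).
#' @return Named list of generated paths plus `planted_tf`, `decoy_tf`,
#'   `planted_term`.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(file.path(dir, "tfbs"), showWarnings = FALSE,
             recursive = TRUE)
  withr::with_seed(spec$seed, {
    parts <- build_fixture_refs(spec)
    planted_dom <- term_domain(parts$planted_term, parts$regdom,
                               parts$annot)
    query <- place_query(spec, parts, planted_dom)
    tf_sites <- place_tf_sites(spec, parts, query, planted_dom)
    write_fixture_files(spec, parts, query, tf_sites, dir)
  })
}

#' Generate a matched pair of bundles for differential analysis
#'
#' Two query BEDs over a shared reference bundle: both contain the same
#' core peaks; each adds unique peaks inside the regulatory domain of its
#' own planted term, where a direction-specific TF's sites are
#' concentrated. Subtracting one query from the other isolates the unique
#' peaks, so each direction-specific TF should dominate only its own
#' direction.
#'
#' @param spec A `fixture_spec`; `frac_peaks_planted` gives the fraction
#'   of peaks unique to each side (the remainder is the shared core).
#' @param dir Output directory.
#' @return Named list of paths plus `planted_tf_a`, `planted_tf_b`,
#'   `planted_term_a`, `planted_term_b`.
#' @export
generate_differential_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(file.path(dir, "tfbs"), showWarnings = FALSE,
             recursive = TRUE)
  withr::with_seed(spec$seed, {
    parts <- build_fixture_refs(spec)
    term_a <- parts$leaves[1]
    term_b <- parts$leaves[2]
    dom_a <- term_domain(term_a, parts$regdom, parts$annot)
    dom_b <- term_domain(term_b, parts$regdom, parts$annot)
    n_unique <- round(spec$frac_peaks_planted * spec$n_peaks)
    n_core <- spec$n_peaks - n_unique
    core <- place_peaks(spec, parts, n_core, NULL)
    uniq_a <- place_peaks(spec, parts, n_unique, dom_a)
    uniq_b <- place_peaks(spec, parts, n_unique, dom_b)
    query_a <- name_peaks(sort_intervals(c(core, uniq_a)))
    query_b <- name_peaks(sort_intervals(c(core, uniq_b)))
    tf_a <- parts$tfs[1]
    tf_b <- parts$tfs[2]
    sites <- list()
    for (tf in parts$tfs) {
      sites[[tf]] <- if (tf == tf_a) {
        planted_sites(spec, parts, uniq_a, dom_a, spec$concentration)
      } else if (tf == tf_b) {
        planted_sites(spec, parts, uniq_b, dom_b, spec$concentration)
      } else {
        uniform_sites(spec, parts, spec$sites_per_tf)
      }
    }
    paths <- write_fixture_files(spec, parts, query_a, sites, dir,
                                 query_name = "query_a.bed")
    paths$query_b <- file.path(dir, "query_b.bed")
    write_bed(query_b, paths$query_b)
    names(paths)[names(paths) == "query"] <- "query_a"
    c(paths, list(planted_tf_a = tf_a, planted_tf_b = tf_b,
                  planted_term_a = term_a, planted_term_b = term_b))
  })
}

# genome, genes, two-level ontology, and derived domains for a spec
build_fixture_refs <- function(spec) {
  chroms <- paste0("chr", seq_len(spec$n_chrom))
  chrom_sizes <- stats::setNames(rep(spec$chrom_len, spec$n_chrom), chroms)
  per_chrom <- ceiling(spec$n_genes / spec$n_chrom)
  gene_chrom <- rep(chroms, each = per_chrom)[seq_len(spec$n_genes)]
  gap <- spec$chrom_len / (per_chrom + 1)
  pos_in_chrom <- unlist(lapply(chroms, function(ch) {
    n <- sum(gene_chrom == ch)
    base <- gap * seq_len(n)
    round(base + stats::runif(n, -gap / 4, gap / 4))
  }), use.names = FALSE)
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(spec$n_genes)),
    chrom = gene_chrom,
    strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
    tss = pmax(pmin(pos_in_chrom, spec$chrom_len - 1), 0),
    stringsAsFactors = FALSE
  )
  leaves <- sprintf("T%02d", seq_len(spec$n_leaf_terms))
  roots <- sprintf("R%02d", seq_len(spec$n_root_terms))
  edges <- data.frame(
    child = leaves,
    parent = roots[(seq_along(leaves) - 1) %% spec$n_root_terms + 1],
    stringsAsFactors = FALSE
  )
  shuffled <- sample(genes$gene_id)
  raw_annot <- data.frame(
    gene_id = shuffled[seq_len(spec$n_leaf_terms * spec$genes_per_term)],
    term_id = rep(leaves, each = spec$genes_per_term),
    stringsAsFactors = FALSE
  )
  regdom <- build_regulatory_domains(genes, chrom_sizes)
  annot <- propagate_annotations(raw_annot, edges)
  # map each TF but the last to a gene; planted TF -> a planted-term gene
  # (so the closed-loop check has a positive case), last TF left unmapped
  tfs <- sprintf("TF%02d", seq_len(spec$n_tfs))
  planted_term <- leaves[1]
  map_tfs <- tfs[-length(tfs)]
  tf_gene_map <- stats::setNames(
    sample(genes$gene_id, length(map_tfs)), map_tfs)
  tf_gene_map[tfs[1]] <- annot$term_genes[[planted_term]][1]
  list(chroms = chroms, chrom_sizes = chrom_sizes, genes = genes,
       edges = edges, raw_annot = raw_annot, regdom = regdom,
       annot = annot, leaves = leaves, roots = roots, tfs = tfs,
       planted_term = planted_term, tf_gene_map = tf_gene_map)
}

# uniform placement of n fixed-length elements inside a region set,
# each element falling entirely within one region interval
place_in_regions <- function(n, regions, len, what = "elements") {
  if (n == 0L) return(GenomicRanges::GRanges())
  regions <- GenomicRanges::reduce(granges_only(regions))
  w <- BiocGenerics::width(regions)
  room <- pmax(w - len + 1, 0)
  if (sum(room) == 0) {
    stop("infeasible placement: no region can hold ", what,
         " of length ", len)
  }
  idx <- sample.int(length(regions), n, replace = TRUE,
                    prob = room / sum(room))
  off <- floor(stats::runif(n) * room[idx])
  GenomicRanges::GRanges(
    seqnames = as.character(GenomeInfoDb::seqnames(regions))[idx],
    ranges = IRanges::IRanges(start = BiocGenerics::start(regions)[idx] +
                                off, width = len)
  )
}

# whole-genome eligible region, one element length away from chrom edges
genome_interior <- function(parts, len) {
  interval_set(parts$chroms, rep(len, length(parts$chroms)),
               unname(parts$chrom_sizes) - len)
}

place_peaks <- function(spec, parts, n, domain) {
  target <- if (is.null(domain)) {
    genome_interior(parts, spec$peak_len)
  } else {
    GenomicRanges::intersect(granges_only(domain),
                             granges_only(genome_interior(parts,
                                                          spec$peak_len)))
  }
  place_in_regions(n, target, spec$peak_len, what = "query peaks")
}

name_peaks <- function(gr) {
  gr <- sort_intervals(gr)
  S4Vectors::mcols(gr)$name <- sprintf("peak%04d", seq_along(gr))
  S4Vectors::mcols(gr)$score <- sample(100:1000, length(gr),
                                       replace = TRUE)
  gr
}

place_query <- function(spec, parts, planted_dom) {
  n_planted <- round(spec$frac_peaks_planted * spec$n_peaks)
  peaks <- c(place_peaks(spec, parts, n_planted, planted_dom),
             place_peaks(spec, parts, spec$n_peaks - n_planted, NULL))
  name_peaks(peaks)
}

uniform_sites <- function(spec, parts, n) {
  place_in_regions(n, genome_interior(parts, spec$site_len),
                   spec$site_len, what = "TF sites")
}

# in-query sites split between the planted-term domain and the remaining
# query bases according to the concentration parameter
planted_sites <- function(spec, parts, query, domain, concentration) {
  n_inq <- round(spec$planted_query_frac * spec$sites_per_tf)
  n_conc <- round(concentration * n_inq)
  qmerged <- GenomicRanges::reduce(granges_only(query))
  q_in_dom <- GenomicRanges::intersect(qmerged, granges_only(domain))
  q_out_dom <- GenomicRanges::setdiff(qmerged, granges_only(domain))
  if (n_conc > 0 && merged_length(q_in_dom) < spec$site_len) {
    stop("infeasible spec: planted-term domain holds no query bases ",
         "wide enough for a binding site")
  }
  sort_intervals(c(
    place_in_regions(n_conc, q_in_dom, spec$site_len, "planted TF sites"),
    place_in_regions(n_inq - n_conc,
                     if (merged_length(q_out_dom) >= spec$site_len)
                       q_out_dom else qmerged,
                     spec$site_len, "planted TF sites"),
    uniform_sites(spec, parts, spec$sites_per_tf - n_inq)
  ))
}

decoy_sites <- function(spec, parts, query) {
  n_inq <- round(spec$decoy_query_frac * spec$sites_per_tf)
  sort_intervals(c(
    place_in_regions(n_inq, query, spec$site_len, "decoy TF sites"),
    uniform_sites(spec, parts, spec$sites_per_tf - n_inq)
  ))
}

place_tf_sites <- function(spec, parts, query, planted_dom) {
  sites <- list()
  for (tf in parts$tfs) {
    sites[[tf]] <- if (tf == parts$tfs[1]) {
      planted_sites(spec, parts, query, planted_dom, spec$concentration)
    } else if (tf == parts$tfs[2]) {
      decoy_sites(spec, parts, query)
    } else {
      uniform_sites(spec, parts, spec$sites_per_tf)
    }
  }
  sites
}

write_fixture_files <- function(spec, parts, query, tf_sites, dir,
                                query_name = "query.bed") {
  paths <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    genes = file.path(dir, "genes.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    ontology = file.path(dir, "ontology.tsv"),
    tf_gene_map = file.path(dir, "tf_gene_map.tsv"),
    query = file.path(dir, query_name),
    tfbs_dir = file.path(dir, "tfbs")
  )
  utils::write.table(
    data.frame(names(parts$chrom_sizes), unname(parts$chrom_sizes)),
    paths$chrom_sizes, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(parts$genes, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(parts$raw_annot, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(parts$edges, paths$ontology, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(names(parts$tf_gene_map), unname(parts$tf_gene_map)),
    paths$tf_gene_map, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_bed(query, paths$query)
  for (tf in names(tf_sites)) {
    gr <- sort_intervals(tf_sites[[tf]])
    S4Vectors::mcols(gr)$name <- sprintf("%s_site%04d", tf,
                                         seq_along(gr))
    S4Vectors::mcols(gr)$score <- sample(1:1000, length(gr),
                                         replace = TRUE)
    write_bed(gr, file.path(paths$tfbs_dir, paste0(tf, ".bed")))
  }
  c(paths, list(planted_tf = parts$tfs[1], decoy_tf = parts$tfs[2],
                planted_term = parts$planted_term))
}
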