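#' Rank dominant TFs for a query region set
#'
#' The full single-sample analysis: select the top enriched ontology terms
#' (the strata), build the TF-by-term enrichment matrix, apply the adaptive
#' significance mask, accumulate stratified partial scores into a score per
#' TF, and attach exact conditional p-values computed down the ranking.
#'
#' @param query `GRanges` of accessible regions (ATAC/DNase peaks).
#' @param tfbs_lib A `tfbs_library`.
#' @param refs A `tf_reference`.
#' @param k_terms Number of ontology terms retained as strata.
#' @param gene_min,gene_max Propagated gene-count bounds for terms.
#' @param top_m Leading p-values inspected by the adaptive threshold.
#' @param conditional Compute conditional p-values (the slow part for large
#'   libraries); when `FALSE` the p-value columns are `NA`.
#' @param n_top_terms Contributing terms reported per TF.
#' @return A `tf_ranking` data.frame (one row per TF in descending score
#'   order) with columns `rank`, `tf`, `score`, `cond_p`, `neg_log10_cp`,
#'   `n_sites_in_query`, `top_terms`, `closed_loop`; the term selection,
#'   enrichment matrix, mask, rank matrix and partial scores are attached
#'   as attributes.
#' @export
rank_tfs <- function(query, tfbs_lib, refs, k_terms = 100,
                     gene_min = 2, gene_max = 500, top_m = 10,
                     conditional = TRUE, n_top_terms = 5) {
  selection <- select_top_terms(query, tfbs_lib, refs, k_terms = k_terms,
                                gene_min = gene_min, gene_max = gene_max)
  message("selected ", nrow(selection), " ontology terms from ",
          length(attr(selection, "query_elems")), " informative elements")
  mat <- compute_tf_term_matrix(attr(selection, "query_elems"), tfbs_lib,
                                selection, refs)
  ranks <- rank_within_terms(mat)
  mask <- significance_mask(mat, top_m = top_m)
  ps <- partial_scores(mask, ranks)
  score <- ps$score
  tf_order <- names(score)[order(-score, names(score), method = "radix")]
  cond <- if (conditional) {
    conditional_pvalues(mask, ranks, tf_order)
  } else {
    stats::setNames(rep(NA_real_, length(tf_order)), tf_order)
  }
  contrib <- lapply(tf_order, top_contributing_terms, partial = ps$partial)
  names(contrib) <- tf_order
  top_terms <- vapply(tf_order, function(tf) {
    tc <- utils::head(contrib[[tf]], n_top_terms)
    if (!nrow(tc)) return("")
    paste(sprintf("%s:%.4g", tc$term_id, tc$partial_score), collapse = ";")
  }, character(1))
  closed <- vapply(tf_order, function(tf) {
    tc <- utils::head(contrib[[tf]], n_top_terms)
    if (!nrow(tc)) return("")
    fl <- vapply(tc$term_id, function(tm) {
      v <- closed_loop_check(tf, tm, refs$annot, refs$tf_gene_map)
      if (is.na(v)) "unavailable" else if (v) "yes" else "no"
    }, character(1))
    paste(sprintf("%s:%s", tc$term_id, fl), collapse = ";")
  }, character(1))
  out <- data.frame(
    rank = seq_along(tf_order),
    tf = tf_order,
    score = unname(score[tf_order]),
    cond_p = unname(cond),
    neg_log10_cp = -log10(unname(cond)),
    n_sites_in_query = unname(mat$n_i[tf_order]),
    top_terms = unname(top_terms),
    closed_loop = unname(closed),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("tf_ranking", "data.frame"),
            selection = selection, matrix = mat, mask = mask,
            ranks = ranks, partial = ps$partial)
}

#' Assemble a run configuration
#'
#' Gathers the file paths and parameters of a file-level run. Paths are
#' checked for existence immediately so a misconfigured run fails before
#' any computation.
#'
#' @param query Path to the query BED.
#' @param tfbs_dir Directory of `<TF>.bed` binding-site tracks.
#' @param genes,annotations,ontology,chrom_sizes Paths to the reference
#'   TSVs (see the reader functions for layouts).
#' @param gaps,tf_gene_map Optional paths.
#' @param out_dir Output directory (created on run).
#' @param k_terms,top_m,gene_min,gene_max,per_tf_cap,basal_up,basal_down,max_extension
#'   Analysis parameters with their defaults.
#' @param seed Integer seed for all randomised steps of a run.
#' @return A `run_config` list.
#' @export
run_config <- function(query, tfbs_dir, genes, annotations, ontology,
                       chrom_sizes, gaps = NULL, tf_gene_map = NULL,
                       out_dir = "tfstrata_out", k_terms = 100, top_m = 10,
                       gene_min = 2, gene_max = 500, per_tf_cap = 5000,
                       basal_up = 5000, basal_down = 1000,
                       max_extension = 1e6, seed = 1) {
  paths <- list(query = query, tfbs_dir = tfbs_dir, genes = genes,
                annotations = annotations, ontology = ontology,
                chrom_sizes = chrom_sizes, gaps = gaps,
                tf_gene_map = tf_gene_map)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input '", nm, "' not found: ", p)
    }
  }
  stopifnot(k_terms >= 1, top_m >= 1, per_tf_cap >= 1,
            gene_min >= 1, gene_max >= gene_min)
  structure(c(paths, list(out_dir = out_dir, k_terms = k_terms,
                          top_m = top_m, gene_min = gene_min,
                          gene_max = gene_max, per_tf_cap = per_tf_cap,
                          basal_up = basal_up, basal_down = basal_down,
                          max_extension = max_extension, seed = seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match the [run_config()] arguments;
#'   relative paths are resolved against the YAML file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("query", "tfbs_dir", "genes", "annotations", "ontology",
                 "chrom_sizes", "gaps", "tf_gene_map")
  for (k in intersect(path_keys, names(vals))) {
    if (!is.null(vals[[k]]) && !grepl("^/", vals[[k]])) {
      vals[[k]] <- file.path(base, vals[[k]])
    }
  }
  do.call(run_config, vals)
}

#' Load the inputs referenced by a run configuration
#' @param config A `run_config`.
#' @return List with `query`, `tfbs_lib`, `refs`.
#' @export
load_run_inputs <- function(config) {
  sizes <- read_chrom_sizes(config$chrom_sizes)
  gaps <- if (!is.null(config$gaps)) read_bed(config$gaps, sizes)
  tmap <- if (!is.null(config$tf_gene_map)) {
    read_tf_gene_map(config$tf_gene_map)
  }
  refs <- reference_set(
    genes = read_gene_models(config$genes),
    chrom_sizes = sizes,
    annotations = read_gene_annotations(config$annotations),
    edges = read_ontology_edges(config$ontology),
    gaps = gaps, tf_gene_map = tmap,
    basal_up = config$basal_up, basal_down = config$basal_down,
    max_extension = config$max_extension
  )
  list(
    query = read_bed(config$query, sizes),
    tfbs_lib = load_tfbs_library(config$tfbs_dir,
                                 per_tf_cap = config$per_tf_cap,
                                 chrom_sizes = sizes),
    refs = refs
  )
}

#' Execute a configured single-sample run
#'
#' Loads all inputs, runs [rank_tfs()], and writes `ranking.tsv` (the main
#' report) and `terms.tsv` (per-term diagnostics) into the output
#' directory. The report header records the resolved parameter set.
#'
#' @param config A `run_config`.
#' @return The `tf_ranking`, invisibly.
#' @export
run_single <- function(config) {
  inputs <- load_run_inputs(config)
  ranking <- rank_tfs(inputs$query, inputs$tfbs_lib, inputs$refs,
                      k_terms = config$k_terms, top_m = config$top_m,
                      gene_min = config$gene_min,
                      gene_max = config$gene_max)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ranking(ranking, file.path(config$out_dir, "ranking.tsv"),
                config = config)
  write_term_table(attr(ranking, "selection"),
                   file.path(config$out_dir, "terms.tsv"))
  invisible(ranking)
}

#' Write / read the main ranking report
#'
#' The TSV carries a display column `neg_log10_cp` rounded to one decimal
#' and the machine-precision `cond_p`; [read_ranking()] restores the full
#' object columns losslessly from the latter.
#'
#' @param ranking A `tf_ranking`.
#' @param path Output TSV path.
#' @param config Optional `run_config` recorded as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(config)) {
    pars <- config[setdiff(names(config), "out_dir")]
    flat <- vapply(pars, function(v) {
      if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
    }, character(1))
    writeLines(sprintf("# %s = %s", names(flat), flat), con)
  }
  tab <- as.data.frame(ranking)
  tab$neg_log10_cp <- round(tab$neg_log10_cp, 1)
  tab$cond_p <- sprintf("%.17g", tab$cond_p)
  tab$score <- sprintf("%.17g", tab$score)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c(
                             rank = "integer", tf = "character",
                             score = "numeric", cond_p = "numeric",
                             neg_log10_cp = "numeric",
                             n_sites_in_query = "integer",
                             top_terms = "character",
                             closed_loop = "character"))
  tab$neg_log10_cp <- -log10(tab$cond_p)
  tab$top_terms[is.na(tab$top_terms)] <- ""
  tab$closed_loop[is.na(tab$closed_loop)] <- ""
  structure(tab, class = c("tf_ranking", "data.frame"))
}

# per-term diagnostics TSV
write_term_table <- function(selection, path) {
  tab <- as.data.frame(selection)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Robustness grid around a base run
#'
#' Re-runs the ranking while varying one input property at a time:
#' subsampling the query to a fraction of its highest-scoring peaks,
#' trimming peaks to a maximum length about their midpoints, and changing
#' the number of selected terms. A stable analysis keeps the same leading
#' TFs across the grid.
#'
#' @param query `GRanges` of accessible regions (with scores if
#'   `fractions` is non-empty).
#' @param tfbs_lib A `tfbs_library`.
#' @param refs A `tf_reference`.
#' @param fractions Numeric vector of subsample fractions (1 = no-op).
#' @param max_lens Integer vector of trim lengths (`NA` = no trim).
#' @param k_values Integer vector of term-count settings.
#' @param k_terms Base number of terms.
#' @param seed Seed for the subsampling tie-break.
#' @param n_top Number of leading TFs tabulated per condition.
#' @param ... Passed to [rank_tfs()].
#' @return Data.frame: `condition`, `value`, `top_tfs`
#'   (comma-separated), `rank1_tf`.
#' @export
run_robustness <- function(query, tfbs_lib, refs,
                           fractions = c(0.7, 0.8, 0.9, 1.0),
                           max_lens = c(200, 500, 1000, NA),
                           k_values = c(50, 100, 150),
                           k_terms = 100, seed = 1, n_top = 5, ...) {
  one <- function(condition, value, q, k) {
    r <- rank_tfs(q, tfbs_lib, refs, k_terms = k, conditional = FALSE, ...)
    data.frame(condition = condition, value = value,
               top_tfs = paste(utils::head(r$tf, n_top), collapse = ","),
               rank1_tf = r$tf[1], stringsAsFactors = FALSE)
  }
  rows <- list(one("base", NA, query, k_terms))
  for (f in fractions) {
    rows <- c(rows, list(one("subsample_fraction", f,
                             subsample_by_score(query, f, seed), k_terms)))
  }
  for (len in max_lens) {
    q <- if (is.na(len)) query else trim_to_midpoint(query, len)
    rows <- c(rows, list(one("trim_max_len", len, q, k_terms)))
  }
  for (k in k_values) {
    rows <- c(rows, list(one("k_terms", k, query, k)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score-vector matrix across samples
#'
#' Stacks per-sample rankings into a TF-by-sample score matrix for
#' downstream embedding or clustering by external tools.
#'
#' @param rankings Named list of `tf_ranking` objects.
#' @return Numeric matrix (TF x sample).
#' @export
score_matrix <- function(rankings) {
  stopifnot(length(rankings) >= 1, !is.null(names(rankings)))
  tfs <- sort(unique(unlist(lapply(rankings, `[[`, "tf"))))
  m <- vapply(rankings, function(r) {
    stats::setNames(r$score, r$tf)[tfs]
  }, numeric(length(tfs)))
  m[is.na(m)] <- 0
  rownames(m) <- tfs
  m
}
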