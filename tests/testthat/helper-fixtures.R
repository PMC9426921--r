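# Shared fixture bundles, generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# default planted bundle written to a session temp dir, plus loaded inputs
default_fixture <- function(seed = 7, concentration = 0.8) {
  key <- sprintf("fx_%d_%g", seed, concentration)
  cached(key, function() {
    dir <- file.path(tempdir(), paste0("tfstrata_", key))
    paths <- generate_fixture(
      fixture_spec(seed = seed, concentration = concentration), dir)
    cfg <- run_config(
      query = paths$query, tfbs_dir = paths$tfbs_dir, genes = paths$genes,
      annotations = paths$annotations, ontology = paths$ontology,
      chrom_sizes = paths$chrom_sizes, tf_gene_map = paths$tf_gene_map,
      out_dir = file.path(dir, "out"), seed = seed)
    list(paths = paths, cfg = cfg, inputs = load_run_inputs(cfg))
  })
}

# full ranking on the default bundle (with conditional p-values)
default_ranking <- function() {
  cached("ranking_7_0.8", function() {
    fx <- default_fixture()
    suppressMessages(rank_tfs(fx$inputs$query, fx$inputs$tfbs_lib,
                              fx$inputs$refs))
  })
}

# tiny deterministic reference: 6 genes, 2 leaf terms + 1 root, 10 kb genome
toy_refs <- function() {
  cached("toy_refs", function() {
    genes <- data.frame(
      gene_id = sprintf("g%d", 1:6),
      chrom = "chr1",
      strand = c("+", "-", "+", "+", "-", "+"),
      tss = c(1000, 2500, 4000, 5500, 7000, 8500)
    )
    sizes <- c(chr1 = 10000)
    annotations <- data.frame(
      gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
      term_id = c("tA", "tA", "tA", "tB", "tB", "tB")
    )
    edges <- data.frame(child = c("tA", "tB"), parent = c("root", "root"))
    reference_set(genes, sizes, annotations, edges,
                  basal_up = 500, basal_down = 100, max_extension = 600)
  })
}
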