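test_that("basal-plus-extension domains follow the association rule", {
  sizes <- c(chr1 = 1e6)
  # lone gene: extension runs the full 1 Mb cap in both directions, clipped
  lone <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                     tss = 1e5)
  d <- build_regulatory_domains(lone, sizes)
  expect_equal(as_bed_df(d), data.frame(chrom = "chr1", start = 0,
                                        end = 1e6))
  # two genes: extension stops at the neighbour's basal boundary
  two <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    strand = c("+", "+"), tss = c(1e5, 2e5))
  d2 <- build_regulatory_domains(two, sizes)
  df <- as_bed_df(d2)[order(S4Vectors::mcols(d2)$name), ]
  expect_equal(df$start, c(0, 101000))
  expect_equal(df$end, c(195000, 1e6))
  # basal domain clipped at the chromosome start
  edge <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                     tss = 3000)
  d3 <- build_regulatory_domains(edge, sizes, max_extension = 0)
  expect_equal(as_bed_df(d3), data.frame(chrom = "chr1", start = 0,
                                         end = 4000))
  # minus strand mirrors the basal domain
  minus <- data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
                      tss = 1e5)
  d4 <- build_regulatory_domains(minus, sizes, max_extension = 0)
  expect_equal(as_bed_df(d4), data.frame(chrom = "chr1", start = 99000,
                                         end = 105000))
  expect_error(build_regulatory_domains(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 2e6),
    sizes), "bounds")
})

test_that("every domain contains its basal domain even when crowded", {
  withr::with_seed(5, {
    sizes <- c(chr1 = 1e5)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
                        strand = sample(c("+", "-"), 30, TRUE),
                        tss = sort(sample(2000:98000, 30)))
    d <- build_regulatory_domains(genes, sizes, basal_up = 5000,
                                  basal_down = 1000, max_extension = 1e4)
    df <- as_bed_df(d)
    nm <- S4Vectors::mcols(d)$name
    g <- genes[match(nm, genes$gene_id), ]
    bs <- pmax(ifelse(g$strand == "+", g$tss - 5000, g$tss - 1000), 0)
    be <- pmin(ifelse(g$strand == "+", g$tss + 1000, g$tss + 5000), 1e5)
    expect_true(all(df$start <= bs & df$end >= be))
    expect_true(all(df$start >= 0 & df$end <= 1e5))
  })
})

test_that("annotation propagation is the ancestor closure and idempotent", {
  raw <- data.frame(gene_id = "g1", term_id = "t")
  edges <- data.frame(child = "t", parent = "r")
  at <- propagate_annotations(raw, edges)
  expect_setequal(at$annotations$term_id, c("t", "r"))
  # no edges: identity
  at0 <- propagate_annotations(raw, edges[0, ])
  expect_equal(at0$annotations$term_id, "t")
  # idempotence: propagating the propagated table changes nothing
  at2 <- propagate_annotations(at$annotations, edges)
  expect_equal(at2$annotations, at$annotations)
  # cycle reported with a witness
  expect_error(propagate_annotations(
    raw, data.frame(child = c("t", "r"), parent = c("r", "t"))),
    "cycle.*t -> r -> t|cycle.*r -> t -> r")
})

test_that("propagation matches breadth-first closure on random DAGs", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      terms <- sprintf("n%02d", 1:30)
      # edges only from lower to higher index: guaranteed acyclic
      pairs <- t(utils::combn(30, 2))
      take <- pairs[stats::runif(nrow(pairs)) < 0.08, , drop = FALSE]
      edges <- data.frame(child = terms[take[, 1]],
                          parent = terms[take[, 2]])
      leaf <- sample(terms, 5)
      raw <- data.frame(gene_id = rep("g1", 5), term_id = leaf)
      got <- propagate_annotations(raw, edges)$annotations$term_id
      want <- unique(unlist(c(leaf, lapply(leaf, bfs_ancestors,
                                           edges = edges))))
      expect_setequal(got, want)
    }
  })
})

test_that("term base probability is a base fraction and monotone in genes", {
  refs <- toy_refs()
  # bit-vector oracle over the 10 kb toy genome
  for (tm in c("tA", "tB", "root")) {
    dom <- term_domain(tm, refs$regdom, refs$annot)
    expect_equal(term_base_probability(tm, refs$regdom, refs$annot,
                                       refs$nongap),
                 sum(base_vector(dom, 10000)) / 10000)
  }
  # the root annotates a superset of genes, so p is at least each leaf's
  p_root <- term_base_probability("root", refs$regdom, refs$annot,
                                  refs$nongap)
  expect_gte(p_root, term_base_probability("tA", refs$regdom, refs$annot,
                                           refs$nongap))
  expect_error(
    term_base_probability("tA", refs$regdom, refs$annot,
                          refs$nongap[integer(0)]), "empty")
})

test_that("gap regions shrink the non-gap universe", {
  sizes <- c(chr1 = 10000)
  expect_equal(merged_length(nongap_regions(sizes)), 10000)
  gaps <- gset(1000, 3000)
  ng <- nongap_regions(sizes, gaps)
  expect_equal(merged_length(ng), 8000)
  expect_equal(merged_length(GenomicRanges::intersect(ng, gaps)), 0)
})

test_that("TFBS library capping keeps the best-scoring sites, stably", {
  withr::with_seed(21, {
    dir <- withr::local_tempdir()
    n <- 600
    s <- sample.int(9000, n) - 1
    gr <- gset(s, s + 10, score = sample(1:20, n, replace = TRUE),
               name = sprintf("site%03d", 1:n))
    write_bed(gr, file.path(dir, "TFX.bed"))
    small <- gset(0, 10, name = "one", score = 5)
    write_bed(small, file.path(dir, "TFY.bed"))
    lib1 <- load_tfbs_library(dir, per_tf_cap = 100)
    lib2 <- load_tfbs_library(dir, per_tf_cap = 100)
    expect_named(lib1, c("TFX", "TFY"))
    expect_length(lib1$TFX, 100)
    expect_length(lib1$TFY, 1)  # under the cap: kept whole
    # deterministic across repeated loads despite score ties at the cutoff
    expect_identical(as_bed_df(lib1$TFX), as_bed_df(lib2$TFX))
    # kept score floor is at least every dropped score
    expect_gte(min(S4Vectors::mcols(lib1$TFX)$score),
               sort(S4Vectors::mcols(gr)$score, decreasing = TRUE)[100])
    expect_error(load_tfbs_library(file.path(dir, "nope")), "nope")
  })
})
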