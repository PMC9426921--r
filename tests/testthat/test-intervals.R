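test_that("element selection keeps whole overlapping elements, once each", {
  elements <- gset(c(0, 20), c(10, 30))
  expect_equal(as_bed_df(select_overlapping_elements(elements,
                                                     gset(5, 6))),
               data.frame(chrom = "chr1", start = 0, end = 10))
  # empty selector selects nothing
  expect_length(select_overlapping_elements(gset(0, 10),
                                            gset(numeric(0), numeric(0))),
                0)
  # a selector covering everything is the identity (idempotence)
  all_sel <- gset(0, 100)
  expect_equal(as_bed_df(select_overlapping_elements(elements, all_sel)),
               as_bed_df(elements))
  # an element overlapped by several selectors appears once
  expect_length(select_overlapping_elements(gset(0, 10),
                                            gset(c(1, 5), c(2, 6))), 1)
})

test_that("mismatched chromosome naming fails loudly", {
  expect_error(
    select_overlapping_elements(gset(0, 10, chrom = "chr1"),
                                gset(0, 10, chrom = "1")),
    "chr1")
})

test_that("base-level subtraction produces maximal clean remnants", {
  expect_equal(as_bed_df(subtract_portions(gset(0, 100), gset(50, 60))),
               data.frame(chrom = "chr1", start = c(0, 60),
                          end = c(50, 100)))
  expect_equal(as_bed_df(subtract_portions(gset(0, 100),
                                           gset(numeric(0), numeric(0)))),
               data.frame(chrom = "chr1", start = 0, end = 100))
  expect_length(subtract_portions(gset(10, 20), gset(0, 30)), 0)
})

test_that("merged_length merges overlap and splits are invisible", {
  expect_equal(merged_length(gset(c(0, 5), c(10, 15))), 15)
  expect_equal(merged_length(gset(numeric(0), numeric(0))), 0)
  # splitting an interval into adjacent pieces leaves the length unchanged
  expect_equal(merged_length(gset(c(0, 40, 70), c(40, 70, 100))),
               merged_length(gset(0, 100)))
})

test_that("interval ops agree with per-base oracles on random sets", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      a <- random_gset(50)
      b <- random_gset(20)
      # selection vs all-pairs scan
      expect_equal(as_bed_df(select_overlapping_elements(a, b)),
                   as_bed_df(overlap_oracle(a, b)))
      # merged length vs bit-vector
      expect_equal(merged_length(a), sum(base_vector(a, 10000)))
      # subtraction vs bit-vector, base by base
      va <- base_vector(a, 10000)
      vb <- base_vector(b, 10000)
      expect_equal(base_vector(subtract_portions(a, b), 10000), va & !vb)
      # conservation: |a \ b| + |a intersect b| = |a|
      expect_equal(merged_length(subtract_portions(a, b)) + sum(va & vb),
                   merged_length(a))
    }
  })
})

test_that("midpoint trimming is exact for even, odd, and short elements", {
  expect_equal(as_bed_df(trim_to_midpoint(gset(0, 1000), 200)),
               data.frame(chrom = "chr1", start = 400, end = 600))
  # short elements untouched
  expect_equal(as_bed_df(trim_to_midpoint(gset(0, 100), 200)),
               data.frame(chrom = "chr1", start = 0, end = 100))
  # odd length: centre floor((0+5)/2)=2, result [2-1, 2+1) = [1, 3)
  expect_equal(as_bed_df(trim_to_midpoint(gset(0, 5), 2)),
               data.frame(chrom = "chr1", start = 1, end = 3))
  # every trimmed element has exactly max_len bases
  withr::with_seed(1, {
    g <- random_gset(100)
    w <- BiocGenerics::width(trim_to_midpoint(g, 50))
    # as a multiset, trimmed widths are the originals capped at max_len
    expect_equal(sort(w), sort(pmin(BiocGenerics::width(g), 50)))
  })
})

test_that("score subsampling keeps top scorers and seeds the tie-break", {
  g <- gset(seq(0, 90, 10), seq(5, 95, 10), score = 10:1)
  kept <- subsample_by_score(g, 0.7, seed = 1)
  expect_length(kept, 7)
  expect_true(all(S4Vectors::mcols(kept)$score >= 4))
  # fraction 1 is the identity
  expect_equal(as_bed_df(subsample_by_score(g, 1, seed = 1)),
               as_bed_df(g))
  # all-tied scores: subsets reproducible per seed, may differ across seeds
  tied <- gset(seq(0, 90, 10), seq(5, 95, 10), score = rep(1, 10))
  s1 <- as_bed_df(subsample_by_score(tied, 0.5, seed = 1))
  s1b <- as_bed_df(subsample_by_score(tied, 0.5, seed = 1))
  expect_identical(s1, s1b)
  expect_equal(nrow(s1), 5)
  # missing scores are an error
  expect_error(subsample_by_score(gset(0, 10), 0.5, seed = 1), "score")
})

test_that("interval construction validates coordinates and bounds", {
  expect_error(gset(-1, 10), "start")
  expect_error(gset(10, 10), "end")
  expect_error(gset(0, 200, chrom_sizes = c(chr1 = 100)), "beyond")
  expect_error(gset(0, 10, chrom = "chrX", chrom_sizes = c(chr1 = 100)),
               "chrX")
  # canonical order is deterministic under input permutation
  g1 <- gset(c(5, 0, 5), c(9, 10, 7))
  g2 <- gset(c(5, 5, 0), c(7, 9, 10))
  expect_identical(as_bed_df(g1), as_bed_df(g2))
})
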