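# fabricate a minimal tf_term_matrix-shaped list for mask/rank unit tests
fake_mat <- function(hyper, binom = hyper) {
  structure(list(tfs = rownames(hyper), terms = colnames(hyper),
                 log_hyper_p = log(hyper), log_binom_p = log(binom)),
            class = "tf_term_matrix")
}

test_that("TF-by-term counts reproduce a hand-built hypergeometric case", {
  sizes <- c(chr1 = 1000)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 100)
  refs <- reference_set(genes, sizes,
                        data.frame(gene_id = "g1", term_id = "tA"),
                        data.frame(child = character(0),
                                   parent = character(0)),
                        basal_up = 100, basal_down = 50,
                        max_extension = 250)
  # domain of tA = [0, 400); 10 distinct sites in the query, 4 in-domain,
  # TFA holds 3 of the 10 with 2 in-domain -> hypergeometric tail 1/3
  expect_equal(as_bed_df(term_domain("tA", refs$regdom, refs$annot)),
               data.frame(chrom = "chr1", start = 0, end = 400))
  tfa <- gset(c(0, 200, 500), c(10, 210, 510))
  tfb <- gset(c(50, 300, 600, 650, 700, 750, 800),
              c(60, 310, 610, 660, 710, 760, 810))
  lib <- structure(list(TFA = tfa, TFB = tfb), class = "tfbs_library")
  query <- gset(0, 1000)
  sel <- structure(data.frame(term_id = "tA", p_term = 0.4),
                   class = c("term_selection", "data.frame"))
  mat <- compute_tf_term_matrix(query, lib, sel, refs)
  expect_equal(mat$N_elem, 10)
  expect_equal(unname(mat$K_j), 4)
  expect_equal(unname(mat$n_i), c(3, 7))
  expect_equal(unname(mat$k[, "tA"]), c(2, 2))
  expect_equal(exp(mat$log_hyper_p["TFA", "tA"]), 1 / 3,
               tolerance = 1e-12)
  expect_equal(exp(mat$log_binom_p["TFA", "tA"]),
               binom_tail_oracle(2, 3, 0.4), tolerance = 1e-12)
  # a TF with no sites in the query scores p = 1 everywhere
  lib0 <- structure(c(lib, list(TF0 = gset(900, 910))),
                    class = "tfbs_library")
  mat0 <- compute_tf_term_matrix(gset(0, 850), lib0, sel, refs)
  expect_equal(unname(mat0$n_i["TF0"]), 0)
  expect_equal(exp(mat0$log_hyper_p["TF0", "tA"]), 1)
  expect_equal(exp(mat0$log_binom_p["TF0", "tA"]), 1)
})

test_that("within-term ranking is deterministic with documented ties", {
  hyper <- matrix(c(0.001, 0.5, 0.01,
                    0.2, 0.2, 0.2), ncol = 2,
                  dimnames = list(c("B", "C", "A"), c("t1", "t2")))
  binom <- matrix(c(0.1, 0.1, 0.1,
                    0.3, 0.1, 0.3), ncol = 2,
                  dimnames = dimnames(hyper))
  rk <- rank_within_terms(fake_mat(hyper, binom))
  expect_equal(rk[, "t1"], c(B = 1L, C = 3L, A = 2L))
  # t2: all hyper tied; C wins on binomial; A beats B alphabetically
  expect_equal(rk[, "t2"], c(B = 3L, C = 1L, A = 2L))
  # permuting TF order leaves the ranking unchanged
  perm <- c(3, 1, 2)
  rk2 <- rank_within_terms(fake_mat(hyper[perm, ], binom[perm, ]))
  expect_equal(rk2[rownames(rk), ], rk)
})

test_that("significance requires passing both adaptive thresholds", {
  tfs <- paste0("TF", 1:10)
  hyper <- matrix(c(1e-10, 1e-9, rep(0.5, 8)), ncol = 1,
                  dimnames = list(tfs, "t1"))
  binom_same <- matrix(c(1e-8, 1e-7, rep(0.6, 8)), ncol = 1,
                       dimnames = list(tfs, "t1"))
  m1 <- significance_mask(fake_mat(hyper, binom_same))
  expect_equal(unname(m1[, 1]), c(TRUE, TRUE, rep(FALSE, 8)))
  # kept by hypergeometric but not binomial -> not significant
  binom_flip <- matrix(c(0.6, 1e-7, 1e-8, rep(0.6, 7)), ncol = 1,
                       dimnames = list(tfs, "t1"))
  m2 <- significance_mask(fake_mat(hyper, binom_flip))
  expect_equal(unname(m2[, 1]), c(FALSE, TRUE, rep(FALSE, 8)))
  # all p equal: the tie rule keeps everyone
  flat <- matrix(rep(0.2, 10), ncol = 1, dimnames = list(tfs, "t1"))
  expect_true(all(significance_mask(fake_mat(flat, flat))))
})

test_that("partial scores follow Significant / (j * Rank) exactly", {
  ranks <- matrix(c(1L, 2L, 3L, 3L, 1L, 2L), ncol = 2,
                  dimnames = list(c("A", "B", "C"), c("t1", "t2")))
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE), ncol = 2,
                 dimnames = dimnames(ranks))
  ps <- partial_scores(mask, ranks)
  expect_equal(ps$partial["A", "t1"], 1)          # j=1, rank 1
  expect_equal(ps$partial["B", "t1"], 1 / 2)
  expect_equal(ps$partial["A", "t2"], 1 / 6)      # j=2, rank 3
  expect_equal(ps$partial["C", "t2"], 0)          # not significant
  expect_equal(unname(ps$score), c(1 + 1 / 6, 0.5, 0))
  # clearing any significance flag can only lower a score
  mask2 <- mask
  mask2["A", "t1"] <- FALSE
  expect_lt(partial_scores(mask2, ranks)$score[["A"]],
            ps$score[["A"]])
})

test_that("contributing terms are ordered by partial score then position", {
  partial <- matrix(c(1 / 3, 1 / 2, 0), nrow = 1,
                    dimnames = list("A", c("t1", "t2", "t3")))
  tc <- top_contributing_terms("A", partial)
  expect_equal(tc$term_id, c("t2", "t1"))
  expect_equal(tc$partial_score, c(1 / 2, 1 / 3))
  # a TF significant nowhere contributes an empty list
  none <- top_contributing_terms("A", matrix(0, 1, 2,
                                             dimnames = list("A",
                                                             c("x", "y"))))
  expect_equal(nrow(none), 0)
})

test_that("closed-loop check distinguishes yes, no, and unavailable", {
  refs <- toy_refs()
  map <- c(TFA = "g1", TFB = "g4")
  expect_true(closed_loop_check("TFA", "tA", refs$annot, map))
  expect_true(closed_loop_check("TFA", "root", refs$annot, map))
  expect_false(closed_loop_check("TFB", "tA", refs$annot, map))
  expect_true(is.na(closed_loop_check("TFZ", "tA", refs$annot, map)))
  expect_true(is.na(closed_loop_check("TFA", "tA", refs$annot, NULL)))
})
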