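test_that("enrichment score follows its defining formula", {
  expect_equal(enrichment_score(7, 7), 0)
  expect_equal(enrichment_score(5, 0), 1)
  expect_equal(enrichment_score(3, 1), 0.5)
  expect_error(enrichment_score(0, 0), "undefined")
  expect_error(enrichment_score(-1, 2), "non-negative")
  g <- expand.grid(m = 0:10, n = 0:10)
  g <- g[g$m + g$n > 0, ]
  E <- enrichment_score(g$m, g$n)
  expect_true(all(E >= -1 & E <= 1))
  expect_equal(E, -enrichment_score(g$n, g$m))   # antisymmetry
})

test_that("junction read filter is an inclusive threshold", {
  ps <- prediction_set("chr1", c(1L, 10L, 20L), c(5L, 15L, 25L), ".",
                       c(1L, 2L, 3L))
  expect_equal(filter_min_junction_reads(ps, 2L)$junction_reads, c(2L, 3L))
  expect_identical(filter_min_junction_reads(ps, 0L)$junction_reads,
                   ps$junction_reads)
  empty <- prediction_set()
  expect_equal(nrow(filter_min_junction_reads(empty, 2L)), 0L)
})

test_that("labelling matches keys across treatments and applies the strict rule", {
  total <- prediction_set("chr1", c(100L, 300L, 500L), c(200L, 400L, 600L),
                          "+", c(2L, 4L, 3L))
  rnaser <- prediction_set("chr1", c(100L, 500L), c(200L, 600L), "-",
                           c(10L, 3L))
  lab <- label_candidates(total, rnaser)
  expect_equal(lab$m, c(10L, 0L, 3L))
  expect_equal(lab$E, c(8 / 12, -1, 0))
  expect_equal(lab$is_true, c(TRUE, FALSE, FALSE))  # E == 0 is false (ties)
  # candidates only in the RNase R set are not part of the universe
  expect_equal(nrow(lab), nrow(total))
})

test_that("summaries are permutation-invariant and reproduce printed rates", {
  mk_labeled <- function(n_total, n_true) {
    total <- prediction_set("chr1", seq_len(n_total) * 10L,
                            seq_len(n_total) * 10L + 5L, ".",
                            rep(2L, n_total))
    rnaser <- prediction_set("chr1", seq_len(n_true) * 10L,
                             seq_len(n_true) * 10L + 5L, ".",
                             rep(9L, n_true))
    label_candidates(total, rnaser)
  }
  s <- summarize_eval(mk_labeled(3488L, 1362L))
  expect_equal(s$n_predicted, 3488L)
  expect_equal(s$n_true, 1362L)
  expect_equal(s$tpr_percent, 39.05)
  expect_equal(summarize_eval(mk_labeled(2854L, 1689L))$tpr_percent, 59.18)

  lab <- mk_labeled(40L, 13L)
  shuffled <- lab[sample.int(nrow(lab)), ]
  expect_equal(summarize_eval(shuffled), summarize_eval(lab))

  expect_equal(summarize_eval(mk_labeled(10L, 0L))$tpr, 0)
  expect_true(is.nan(summarize_eval(lab[0L, ])$tpr))
})

test_that("algorithm combination counts key support", {
  mk <- function(starts, true = TRUE) {
    total <- prediction_set("chr1", starts, starts + 50L, ".",
                            rep(3L, length(starts)))
    rnaser <- if (true) total else prediction_set()
    lab <- label_candidates(total, if (true) {
      prediction_set("chr1", starts, starts + 50L, ".",
                     rep(9L, length(starts)))
    } else prediction_set())
    lab
  }
  A <- mk(c(10L, 20L)); B <- mk(c(20L, 30L)); C <- mk(20L)
  comb <- combine_algorithms(list(A = A, B = B, C = C), 2L)
  expect_equal(comb$labeled$start, 20L)
  expect_equal(sort(comb$membership$support), c(1L, 1L, 3L))
  expect_equal(nrow(combine_algorithms(list(A, B, C), 1L)$labeled), 3L)
  expect_equal(combine_algorithms(list(A, B, C), 3L)$labeled$start, 20L)
  expect_error(combine_algorithms(list(A, B), 3L), "min_support")

  # per-candidate values come from the first set containing the key
  A2 <- A; A2$m[A2$start == 20L] <- 99L
  comb2 <- combine_algorithms(list(B, A2), 2L)
  expect_equal(comb2$labeled$m, B$m[B$start == 20L])
})

test_that("support-filtered combination is monotone when noise is private", {
  # construct sets where false positives are algorithm-private
  shared <- prediction_set("chr1", c(10L, 30L), c(20L, 40L), ".", c(3L, 3L))
  rnaser <- prediction_set("chr1", c(10L, 30L), c(20L, 40L), ".", c(9L, 9L))
  mk <- function(private_start) {
    tot <- prediction_set("chr1", c(10L, 30L, private_start),
                          c(20L, 40L, private_start + 10L), ".",
                          c(3L, 3L, 3L))
    label_candidates(tot, rnaser)
  }
  sets <- list(mk(100L), mk(200L), mk(300L))
  tprs <- vapply(1:3, function(s)
    summarize_eval(combine_algorithms(sets, s)$labeled)$tpr, numeric(1L))
  expect_true(all(diff(tprs) >= 0))
  expect_equal(tprs[3], 1)
})

test_that("top-k re-ranking is deterministic and enriches planted truth", {
  total <- prediction_set("chr1", c(10L, 30L, 50L, 70L), c(20L, 40L, 60L, 80L),
                          ".", c(5L, 5L, 5L, 5L))
  rnaser <- prediction_set("chr1", 10L, 20L, ".", 50L)
  lab <- label_candidates(total, rnaser)
  tk <- top_k_by_reads(lab, 2L)
  expect_equal(tk$subset$start, c(10L, 30L))      # all tied: key order
  expect_equal(top_k_by_reads(lab, 99L)$tpr, summarize_eval(lab)$tpr)

  # planted construction: true candidates get higher counts
  n <- 40L
  true_n <- rep(c(20L, 3L), each = n / 2)
  total <- prediction_set("chr1", seq_len(n) * 100L, seq_len(n) * 100L + 9L,
                          ".", true_n)
  rnaser <- prediction_set("chr1", seq_len(n / 2) * 100L,
                           seq_len(n / 2) * 100L + 9L, ".", 60L)
  lab <- label_candidates(total, rnaser)
  expect_gte(top_k_by_reads(lab, 10L)$tpr, summarize_eval(lab)$tpr)
  expect_equal(top_k_by_reads(lab, 10L)$tpr, 1)
  expect_error(top_k_by_reads(lab, 0L), "k must be")
})
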