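test_that("transcriptome simulation is deterministic and respects invariants", {
  cfg <- small_config()
  tx1 <- simulate_transcriptome(cfg)
  tx2 <- simulate_transcriptome(cfg)
  expect_identical(tx1$genome, tx2$genome)
  expect_identical(tx1$transcripts, tx2$transcripts)

  expect_equal(anyDuplicated(tx1$circs$key), 0L)
  expect_true(all(tx1$circs$length >= 2L * cfg$read_length))
  expect_true(all(tx1$transcripts$start >= 1L &
                  tx1$transcripts$end <= cfg$genome_length))

  # loci do not overlap (circs sit inside their own host by design)
  t <- tx1$transcripts
  loci <- t[t$type != "circ", ]
  loci <- loci[order(loci$start), ]
  expect_true(all(loci$start[-1L] > loci$end[-nrow(loci)]))

  expect_error(simulate_transcriptome(small_config(genome_length = 20000L)),
               "too short")
  expect_error(sim_config(circ_len_range = c(150L, 400L)), "read_length")
})

test_that("a transcriptome without planted circles yields no predictions", {
  cfg <- small_config(n_circ = 0L, n_decoys = 0L)
  tx <- simulate_transcriptome(cfg)
  expect_equal(nrow(tx$circs), 0L)
  sim <- simulate_reads(tx, cfg, "total")
  expect_false(any(sim$truth$is_circ))
  preds <- pseudo_predict(sim$pairs, tx, cfg)
  expect_equal(nrow(preds), 0L)
})

test_that("read simulation is deterministic and treatment-aware", {
  cfg <- small_config()
  tx <- simulate_transcriptome(cfg)
  a <- simulate_reads(tx, cfg, "total")
  b <- simulate_reads(tx, cfg, "total")
  expect_identical(a$pairs$mate1$bases, b$pairs$mate1$bases)
  expect_identical(a$truth, b$truth)

  rn <- simulate_reads(tx, cfg, "rnaser")
  # linear depletion: circ-read fraction strictly higher after treatment
  expect_gt(mean(rn$truth$is_circ), mean(a$truth$is_circ))
  expect_lt(nrow(rn$truth), cfg$depth * cfg$rnaser_depth_factor)

  # complete digestion removes every linear-derived pair
  cfg0 <- small_config(rnaser_linear_survival = 0)
  tx0 <- simulate_transcriptome(cfg0)
  rn0 <- simulate_reads(tx0, cfg0, "rnaser")
  expect_true(all(rn0$truth$is_circ))

  expect_true(all(nchar(a$pairs$mate1$bases) == cfg$read_length))
  expect_equal(anyDuplicated(a$truth$read_id), 0L)
})

test_that("BSJ-spanning read counts match the uniform-start expectation", {
  C <- 500L
  cfg <- sim_config(n_circ = 1L, n_linear = 2L, n_decoys = 0L, host_prob = 0,
                    depth = 20000L, genome_length = 50000L,
                    circ_len_meanlog = log(C), circ_len_sdlog = 0,
                    circ_len_range = c(C, C),
                    circ_cov_median = 200, circ_cov_cap = 200, seed = 5L)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx, cfg, "total")
  circ <- sim$truth[sim$truth$is_circ, ]
  n <- nrow(circ)
  expect_gt(n, 100L)
  # each emitted mate spans the junction with >= min_overlap flanks for
  # exactly L - 2*mo + 1 of the C equally likely fragment anchors
  p <- (cfg$read_length - 2L * cfg$min_overlap + 1L) / C
  for (cnt in c(sum(circ$spans1), sum(circ$spans2))) {
    expect_gt(cnt, n * p - 4 * sqrt(n * p * (1 - p)))
    expect_lt(cnt, n * p + 4 * sqrt(n * p * (1 - p)))
  }
  # the anchor matcher recovers exactly the BSJ-spanning pairs on clean reads
  preds <- pseudo_predict(sim$pairs, tx, cfg)
  expect_equal(preds$junction_reads[preds$start == tx$circs$start],
               sum(circ$spans_bsj))
})

test_that("probe matching tolerates mismatches like the reference matcher", {
  cfg <- small_config()
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx, cfg, "total")
  noisy <- inject_errors(sim$pairs, 3L, 9L)
  core <- substr(tx$genome, tx$decoys$probe_point[1] - cfg$min_overlap + 1L,
                 tx$decoys$probe_point[1] + cfg$min_overlap)
  reads <- Biostrings::DNAStringSet(noisy$mate1$bases)
  ref <- Biostrings::vcountPattern(core, reads,
                                   max.mismatch = cfg$max_mismatch) > 0
  hits <- circbench:::.match_probe_cores(noisy$mate1$bases, core,
                                         cfg$max_mismatch)
  expect_equal(sort(unique(hits$read)), which(ref))
})

test_that("heavy read errors reduce detections; clean reads maximise them", {
  cfg <- small_config()
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx, cfg, "total")
  clean <- pseudo_predict(sim$pairs, tx, cfg)
  noisy <- pseudo_predict(inject_errors(sim$pairs, 20L, 13L), tx, cfg)
  n_detected <- function(p) nrow(filter_min_junction_reads(p, 2L))
  expect_lt(n_detected(noisy), n_detected(clean))
})

test_that("region read counts add linear coverage at the splice sites", {
  cfg <- small_config()
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_reads(tx, cfg, "total")
  preds <- region_read_counts(pseudo_predict(sim$pairs, tx, cfg), sim$truth)
  expect_true(all(preds$region_reads >= preds$junction_reads))
  hosted <- preds[candidate_key(preds$chrom, preds$start, preds$end) %in%
                  tx$circs$key[!is.na(tx$circs$host_id)], ]
  if (nrow(hosted)) expect_true(any(hosted$region_reads >
                                    hosted$junction_reads))
})

test_that("benchmark export writes a complete, reproducible bundle", {
  cfg <- small_config(depth = 4000L)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- make_benchmark(cfg, d1)
  m2 <- make_benchmark(cfg, d2)
  expected <- c("total_R1.fastq", "total_R2.fastq", "rnaser_R1.fastq",
                "rnaser_R2.fastq", "truth_total.tsv", "truth_rnaser.tsv",
                "preds_total.tsv", "preds_rnaser.tsv", "manifest.json")
  expect_true(all(expected %in% list.files(d1)))
  expect_equal(m1$counts$n_circ_planted, cfg$n_circ)
  for (f in setdiff(expected, "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ps <- parse_prediction_table(file.path(d1, "preds_total.tsv"), "bedlike")
  expect_gt(nrow(ps), 0L)
  expect_true(all(!is.na(ps$region_reads)))
})
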