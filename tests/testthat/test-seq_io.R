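test_that("FASTQ round-trip is byte-identical, plain and gzipped", {
  recs <- fastq_records(
    c("r1", "r2 extra text", "r3/1"),
    c("ACGT", "NNACGTNN", "AAAA"),
    c("IIII", "!!IIII#%", "FFFF"))
  for (ext in c(".fastq", ".fastq.gz")) {
    f <- tempfile(fileext = ext)
    write_fastq(recs, f)
    back <- read_fastq(f)
    expect_equal(back$read_id, recs$read_id)
    expect_equal(back$bases, recs$bases)
    expect_equal(back$qualities, recs$qualities)
  }
  # gzip is detected from magic bytes even with a lying extension
  f_gz <- tempfile(fileext = ".fastq")
  con <- gzfile(f_gz, "wt")
  writeLines(c("@x", "ACGT", "+", "IIII"), con)
  close(con)
  expect_equal(read_fastq(f_gz)$bases, "ACGT")
})

test_that("empty FASTQ streams round-trip", {
  f <- tempfile(fileext = ".fastq")
  write_fastq(fastq_records(character(), character()), f)
  expect_true(file.exists(f))
  out <- read_fastq(f)
  expect_equal(nrow(out), 0L)
})

test_that("malformed FASTQ is rejected with the record index", {
  f <- write_lines_tmp(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "II"))
  expect_error(read_fastq(f), "record 2.*lengths differ")
  f <- write_lines_tmp(c("r1", "ACGT", "+", "IIII"))
  expect_error(read_fastq(f), "record 1.*'@'")
  f <- write_lines_tmp(c("@r1", "ACGT", "+"))
  expect_error(read_fastq(f), "multiple of 4")
  expect_error(read_fastq(tempfile()), "no such file")
})

test_that("fastq_records enforces its invariants", {
  expect_error(fastq_records("r1", "ACGT", "III"), "lengths differ")
  expect_error(fastq_records("r1", "ACGU"), "outside")
  expect_error(fastq_records("r1", "ACGT", "IIII", mate = 3L), "mate")
})

test_that("bedlike tables shift 0-based starts and round-trip", {
  f <- write_lines_tmp("chr1\t99\t200\t+\t5")
  ps <- parse_prediction_table(f, "bedlike")
  expect_equal(ps$start, 100L)
  expect_equal(ps$end, 200L)
  expect_equal(ps$junction_reads, 5L)
  expect_equal(splice_distance(ps$start, ps$end), 101L)

  # idempotence under re-serialisation
  ps0 <- prediction_set("chr2", c(10L, 5L), c(30L, 9L), c("+", "-"),
                        c(3L, 7L), region_reads = c(12L, NA))
  f2 <- tempfile()
  write_prediction_table(ps0, f2)
  ps1 <- parse_prediction_table(f2, "bedlike")
  f3 <- tempfile()
  write_prediction_table(ps1, f3)
  expect_identical(readLines(f2), readLines(f3))
  expect_equal(ps1$start, ps0$start)
  expect_equal(ps1$junction_reads, ps0$junction_reads)
})

test_that("CIRI tables merge duplicate junctions and validate coordinates", {
  f <- write_lines_tmp(c(
    "circRNA_ID\tchr\tcircRNA_start\tcircRNA_end\t#junction_reads\tstrand",
    "c1\tchr1\t100\t200\t2\t+",
    "c2\tchr1\t100\t200\t3\t-",
    "c3\tchr2\t50\t80\t4\t+"))
  ps <- parse_prediction_table(f, "ciri")
  expect_equal(nrow(ps), 2L)
  merged <- ps[ps$chrom == "chr1", ]
  expect_equal(merged$junction_reads, 5L)      # counts summed
  expect_equal(merged$strand, "+")             # first-seen strand kept

  f_bad <- write_lines_tmp(c(
    "circRNA_ID\tchr\tcircRNA_start\tcircRNA_end\t#junction_reads",
    "c1\tchr1\t300\t200\t2"))
  expect_error(parse_prediction_table(f_bad, "ciri"), "start > end")
  f_nohdr <- write_lines_tmp("chr1\t1\t2\t+\t5")
  expect_error(parse_prediction_table(f_nohdr, "ciri"), "circRNA_ID")
})

test_that("KNIFE junction ids are parsed, with and without gene annotations", {
  f <- write_lines_tmp(c(
    "junction\treads",
    "chr1|100|200\t4",
    "chr2|GENE1:500|GENE2:300|circ|rev\t6"))
  ps <- parse_prediction_table(f, "knife")
  expect_equal(nrow(ps), 2L)
  expect_equal(ps$start[ps$chrom == "chr1"], 100L)
  r2 <- ps[ps$chrom == "chr2", ]
  expect_equal(c(r2$start, r2$end), c(300L, 500L))  # normalised start <= end
  expect_equal(r2$strand, "-")
  expect_equal(r2$junction_reads, 6L)

  f_bad <- write_lines_tmp(c("chr1|100|200\t4", "chr1|x|200\t2"))
  expect_error(parse_prediction_table(f_bad, "knife"), "line 2")
})

test_that("junction keys are strand-blind and order-independent", {
  a <- prediction_set(c("chr1", "chr1"), c(100L, 100L), c(200L, 200L),
                      c("+", "-"), c(2L, 3L))
  expect_equal(nrow(a), 1L)
  expect_equal(a$junction_reads, 5L)

  sh <- prediction_set(c("chr2", "chr1"), c(5L, 1L), c(6L, 2L), ".", c(1L, 1L))
  expect_equal(sh$chrom, c("chr1", "chr2"))  # sorted by key
})

test_that("mate pairing is validated", {
  p <- random_pairs(10L)
  expect_error(read_pairs(p$mate1, p$mate2[1:9, ]), "record count")
  m2 <- p$mate2
  m2$read_id[3] <- "other"
  expect_error(read_pairs(p$mate1, m2), "ids do not match")
  # /1 //2 suffixes are tolerated
  m1 <- p$mate1; m2 <- p$mate2
  m1$read_id <- paste0(m1$read_id, "/1")
  m2$read_id <- paste0(m2$read_id, "/2")
  expect_s3_class(read_pairs(m1, m2), "read_pairs")
})
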