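# Shared fixtures, all built in code.

# random read set over {A,C,G,T}
random_reads <- function(n, len = 100L, seed = 1L, prefix = "r") {
  set.seed(seed)
  fastq_records(
    sprintf("%s%04d", prefix, seq_len(n)),
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1L)),
    mate = 1L)
}

random_pairs <- function(n, len = 100L, seed = 1L) {
  m1 <- random_reads(n, len, seed)
  m2 <- random_reads(n, len, seed + 1L)
  m2$read_id <- m1$read_id
  m1$mate <- 1L
  m2$mate <- 2L
  read_pairs(m1, m2)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# small, fast synthetic study configuration
small_config <- function(seed = 7L, n_circ = 12L, n_decoys = 5L,
                         depth = 15000L, genome_length = 200000L, ...) {
  sim_config(n_circ = n_circ, n_linear = 20L, n_decoys = n_decoys,
             depth = depth, genome_length = genome_length, seed = seed, ...)
}

# brute-force two-sample K-S statistic: sup over pooled points of |Fx - Fy|
ks_brute_D <- function(x, y) {
  pool <- unique(c(x, y))
  max(vapply(pool, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1L)))
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
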