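# The three "imperfect data" simulators: single-end projection, read-pair
# subsampling (depth titration) and per-read base substitution errors.
# All three are deterministic given their seed, preserve read order, and never
# break mate pairing.

#' Specify a degradation
#'
#' A validated description of one degradation condition, consumed by
#' [run_pipeline()]. Exactly the fields required by `mode` are used:
#' `which_mate` for `"single_end"`, `rate` for `"subsample"`, `k_errors` for
#' `"errors"`.
#'
#' @param mode `"single_end"`, `"subsample"` or `"errors"`.
#' @param which_mate Mate (1 or 2) to keep in single-end mode.
#' @param rate Pair retention probability in `(0, 1]` for subsample mode.
#' @param k_errors Non-negative number of base substitutions per read.
#' @return A list of class `degrade_spec`.
#' @export
degrade_spec <- function(mode = c("single_end", "subsample", "errors"),
                         which_mate = NULL, rate = NULL, k_errors = NULL) {
  mode <- match.arg(mode)
  spec <- switch(mode,
    single_end = {
      if (is.null(which_mate) || !which_mate %in% c(1L, 2L))
        stop_("single_end mode requires which_mate in {1, 2}")
      list(mode = mode, which_mate = as.integer(which_mate))
    },
    subsample = {
      if (is.null(rate) || !is.finite(rate) || rate <= 0 || rate > 1)
        stop_("subsample mode requires rate in (0, 1]")
      list(mode = mode, rate = as.numeric(rate))
    },
    errors = {
      if (is.null(k_errors) || k_errors < 0)
        stop_("errors mode requires k_errors >= 0")
      list(mode = mode, k_errors = as.integer(k_errors))
    }
  )
  structure(spec, class = "degrade_spec")
}

degrade_label <- function(spec) {
  switch(spec$mode,
    single_end = sprintf("single_end_%d", spec$which_mate),
    subsample = sprintf("subsample_%g", spec$rate),
    errors = sprintf("errors_%d", spec$k_errors)
  )
}

#' Project paired-end reads to single-end
#'
#' Simulates a single-end sequencing run by keeping exactly one mate of every
#' pair, order preserved, records unmodified.
#'
#' @param pairs A [read_pairs] object.
#' @param which_mate 1 or 2.
#' @return A [fastq_records] data frame.
#' @export
split_single_end <- function(pairs, which_mate) {
  if (!is_read_pairs(pairs)) pairs <- read_pairs(pairs$mate1, pairs$mate2)
  if (!which_mate %in% c(1L, 2L)) stop_("which_mate must be 1 or 2")
  if (which_mate == 1L) pairs$mate1 else pairs$mate2
}

#' Subsample read pairs
#'
#' Simulates reduced sequencing depth: each pair is kept independently with
#' probability `rate` (both mates kept or both dropped), relative order
#' preserved. Bernoulli per-pair sampling rather than exact-count sampling
#' keeps the operation streaming-friendly and order-independent.
#'
#' @param pairs A [read_pairs] object.
#' @param rate Retention probability in `(0, 1]`.
#' @param seed Integer seed; the same seed reproduces the same kept set.
#' @return A [read_pairs] object.
#' @export
subsample_pairs <- function(pairs, rate, seed) {
  if (!is_read_pairs(pairs)) pairs <- read_pairs(pairs$mate1, pairs$mate2)
  if (!is.finite(rate) || rate <= 0 || rate > 1)
    stop_("rate must be in (0, 1]")
  keep <- with_seed(seed, stats::runif(n_pairs(pairs)) < rate)
  read_pairs(pairs$mate1[keep, , drop = FALSE],
             pairs$mate2[keep, , drop = FALSE])
}

# substitution table: row = original base, column = uniform draw in 1..4;
# every alternative differs from the original ("A is replaced by T, C, G or N");
# an original N is replaced by a uniform draw from {A,C,G,T}.
SUBST_TABLE <- local({
  ab <- c("A", "C", "G", "T", "N")
  t(vapply(ab, function(b) setdiff(ab, b)[1:4], character(4L)))
})

mutate_records <- function(records, k_errors) {
  n <- nrow(records)
  if (n == 0L || k_errors == 0L) return(records)
  lens <- nchar(records$bases)
  big <- charToRaw(paste(records$bases, collapse = ""))
  offset <- c(0L, cumsum(lens))
  # Fixed RNG consumption per read (full position permutation + one
  # replacement draw per position) regardless of k: with the same seed the
  # mutated position sets are nested across k, so per-read damage — and hence
  # every downstream detection count — is monotone in k.
  pos <- vector("list", n)
  repl <- vector("list", n)
  for (i in seq_len(n)) {
    perm <- sample.int(lens[i])
    u <- sample.int(4L, lens[i], replace = TRUE)
    k <- min(k_errors, lens[i])
    pos[[i]] <- perm[seq_len(k)] + offset[i]
    repl[[i]] <- u[seq_len(k)]
  }
  gpos <- unlist(pos)
  u <- unlist(repl)
  orig <- rawToChar(big[gpos], multiple = TRUE)
  oi <- match(orig, rownames(SUBST_TABLE))
  big[gpos] <- charToRaw(paste(SUBST_TABLE[cbind(oi, u)], collapse = ""))
  all_str <- rawToChar(big)
  records$bases <- substring(all_str, offset[-length(offset)] + 1L,
                             offset[-1L])
  records
}

#' Inject base substitution errors
#'
#' Simulates reduced sequencing quality: in every read, exactly
#' `min(k_errors, read length)` distinct positions are chosen uniformly
#' without replacement and each chosen base is replaced by a character drawn
#' uniformly from `{A,C,G,T,N}` minus the original (an original `N` becomes a
#' uniform draw from `{A,C,G,T}`). Quality strings, read ids, count and order
#' are unchanged, so the effect of base errors is isolated from quality-score
#' effects. Deterministic given `seed`; for a fixed seed the mutated positions
#' are nested across increasing `k_errors`.
#'
#' @param pairs A [read_pairs] object, or a single [fastq_records] data frame.
#' @param k_errors Number of substitutions per read.
#' @param seed Integer seed.
#' @return Same shape as `pairs`.
#' @export
inject_errors <- function(pairs, k_errors, seed) {
  if (k_errors < 0) stop_("k_errors must be >= 0")
  k_errors <- as.integer(k_errors)
  if (is_read_pairs(pairs)) {
    with_seed(seed, {
      m1 <- mutate_records(pairs$mate1, k_errors)
      m2 <- mutate_records(pairs$mate2, k_errors)
      read_pairs(m1, m2)
    })
  } else {
    with_seed(seed, mutate_records(pairs, k_errors))
  }
}
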