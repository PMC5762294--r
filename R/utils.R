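#' @useDynLib circbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a global seed and a label
#'
#' All randomness in the pipeline flows from one global seed; each stage draws
#' from a stream seeded by a deterministic hash of `(seed, tag)`, so adding or
#' reordering stages never perturbs the others. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param tag Character stage label.
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1L, "reads_total")
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(tag) == 1L)
  m <- 2147483647          # 2^31 - 1, keeps all arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# round half up (base round() is banker's rounding)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
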