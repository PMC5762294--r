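# Truth labelling by RNase R enrichment. A candidate predicted from total RNA
# with junction reads n is matched by its (chrom, start, end) key against the
# RNase-R-treated prediction (junction reads m) and scored
#   E = (m - n) / (m + n),
# in [-1, 1]. CircRNAs survive RNase R while linear RNAs are digested, so
# E > 0 (strictly) defines a true positive; a candidate absent from the
# RNase-R set gets m = 0, E = -1. The evaluation universe is the total-RNA
# prediction set: candidates seen only after RNase R treatment are not part
# of it (true positive rates are computed over what total RNA predicted).

#' Filter candidates by junction read support
#'
#' Retains candidates with `junction_reads >= min_reads`; the standard
#' pre-filter is two junction-spanning reads.
#'
#' @param preds A [prediction_set].
#' @param min_reads Inclusive threshold (default 2).
#' @return A [prediction_set].
#' @export
filter_min_junction_reads <- function(preds, min_reads = 2L) {
  if (min_reads < 0) stop_("min_reads must be >= 0")
  keep <- preds$junction_reads >= min_reads
  out <- preds[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(preds), sample_id = attr(preds, "sample_id"))
}

#' RNase R enrichment score
#'
#' `E = (m - n) / (m + n)` where `m` is a candidate's junction read count in
#' the RNase-R-treated library and `n` its count in the total-RNA library.
#' Antisymmetric in its arguments and bounded in `[-1, 1]`. Vectorised.
#'
#' @param m,n Non-negative integer read counts with `m + n > 0`.
#' @return Numeric score(s) in `[-1, 1]`.
#' @examples
#' enrichment_score(3, 1)   # 0.5
#' enrichment_score(5, 0)   # 1
#' @export
enrichment_score <- function(m, n) {
  if (any(m < 0) || any(n < 0)) stop_("read counts must be non-negative")
  if (any(m + n == 0))
    stop_("enrichment score undefined for m + n == 0")
  (m - n) / (m + n)
}

#' Label total-RNA candidates against an RNase R treated run
#'
#' Produces one labelled row per candidate in `total`: `n` is its total-RNA
#' junction read count, `m` the count of the matching key in `rnaser` (0 when
#' absent, giving `E = -1`), and `is_true = (E > 0)` — a strict inequality, so
#' ties (`m == n`) are conservatively false. Both inputs should already be
#' filtered with [filter_min_junction_reads()].
#'
#' @param total [prediction_set] from the total-RNA library.
#' @param rnaser [prediction_set] from the RNase-R-treated library.
#' @return A data frame of class `circ_labels` with columns `chrom`, `start`,
#'   `end`, `strand`, `n`, `m`, `E`, `is_true` and `region_reads` (carried
#'   from `total`, `NA` when unknown).
#' @export
label_candidates <- function(total, rnaser) {
  key_t <- candidate_key(total$chrom, total$start, total$end)
  key_r <- candidate_key(rnaser$chrom, rnaser$start, rnaser$end)
  m <- rnaser$junction_reads[match(key_t, key_r)]
  m[is.na(m)] <- 0L
  n <- total$junction_reads
  E <- ifelse(m + n > 0, (m - n) / (m + n), -1)
  out <- data.frame(
    chrom = total$chrom, start = total$start, end = total$end,
    strand = total$strand, n = n, m = m, E = E, is_true = E > 0,
    region_reads = total$region_reads, stringsAsFactors = FALSE
  )
  structure(out, class = c("circ_labels", "data.frame"))
}

#' Summarise a labelled candidate set
#'
#' Counts predictions, overlap with the RNase-R run (`m > 0`) and true
#' positives (`E > 0`), and computes the true positive rate
#' `tpr = n_true / n_predicted` (reported as `NaN` when nothing was
#' predicted). `tpr_percent` is the percentage rounded half-up to 2 decimals,
#' the convention used for printed rates such as 39.05%.
#'
#' @param labeled A `circ_labels` data frame from [label_candidates()].
#' @return A list of class `circ_eval` with fields `n_predicted`,
#'   `n_overlap_with_rnaser`, `n_true`, `tpr`, `tpr_percent`.
#' @examples
#' total <- prediction_set("chr1", c(100, 300), c(200, 500), "+", c(2, 4))
#' rnaser <- prediction_set("chr1", 100, 200, "+", 10)
#' summarize_eval(label_candidates(total, rnaser))
#' @export
summarize_eval <- function(labeled) {
  n_pred <- nrow(labeled)
  n_true <- sum(labeled$is_true)
  tpr <- if (n_pred > 0) n_true / n_pred else NaN
  structure(list(
    n_predicted = n_pred,
    n_overlap_with_rnaser = sum(labeled$m > 0),
    n_true = n_true,
    tpr = tpr,
    tpr_percent = round_half_up(100 * tpr, 2L)
  ), class = "circ_eval")
}

#' @export
print.circ_eval <- function(x, ...) {
  cat(sprintf(
    "<circ_eval> %d predicted | %d overlap RNase R | %d true | TPR %.2f%%\n",
    x$n_predicted, x$n_overlap_with_rnaser, x$n_true, x$tpr_percent))
  invisible(x)
}

#' Combine labelled sets from several algorithms
#'
#' Keeps junction keys supported by at least `min_support` of the input sets;
#' per-candidate values (`n`, `m`, `E`, `is_true`) are taken from the first
#' set, in input order, containing the key. The full membership table (one
#' logical column per input set plus the support count) is returned alongside,
#' from which every Venn region count is derivable.
#'
#' @param sets A list of `circ_labels` data frames (named, ideally).
#' @param min_support Integer in `[1, length(sets)]`.
#' @return A list with elements `labeled` (a `circ_labels` data frame) and
#'   `membership` (data frame: `key`, one logical column per set, `support`).
#' @export
combine_algorithms <- function(sets, min_support) {
  if (!length(sets)) stop_("need at least one labelled set")
  if (min_support < 1 || min_support > length(sets))
    stop_("min_support must be in [1, %d]", length(sets))
  nm <- names(sets) %||% paste0("set", seq_along(sets))
  nm[!nzchar(nm)] <- paste0("set", which(!nzchar(nm)))
  keys <- lapply(sets, function(s) candidate_key(s$chrom, s$start, s$end))
  all_keys <- sort(unique(unlist(keys)))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys),
                   dimnames = list(NULL, nm))
  support <- rowSums(member)
  membership <- data.frame(key = all_keys, member, support = support,
                           stringsAsFactors = FALSE, check.names = FALSE)
  keep <- all_keys[support >= min_support]
  first_set <- apply(member[support >= min_support, , drop = FALSE], 1L,
                     which.max)
  rows <- lapply(seq_along(keep), function(i) {
    s <- sets[[first_set[i]]]
    s[keys[[first_set[i]]] == keep[i], , drop = FALSE][1L, , drop = FALSE]
  })
  labeled <- if (length(rows)) do.call(rbind, rows) else
    sets[[1L]][0L, , drop = FALSE]
  rownames(labeled) <- NULL
  list(labeled = structure(labeled, class = c("circ_labels", "data.frame")),
       membership = membership)
}

#' Re-rank candidates by read count and keep the top k
#'
#' Sorts by total-RNA junction read count `n` (descending), breaking ties by
#' lexicographic key order so the result is deterministic and independent of
#' input order, and returns the first `min(k, size)` candidates with their
#' true positive rate. Selecting high-count candidates is the re-ranking
#' step that trades yield for precision.
#'
#' @param labeled A `circ_labels` data frame.
#' @param k Number of candidates to keep (`>= 1`).
#' @return A list with `subset` (a `circ_labels` data frame) and `tpr`.
#' @export
top_k_by_reads <- function(labeled, k) {
  if (k < 1) stop_("k must be >= 1")
  key <- candidate_key(labeled$chrom, labeled$start, labeled$end)
  o <- order(-labeled$n, key)
  sub <- labeled[o[seq_len(min(k, nrow(labeled)))], , drop = FALSE]
  rownames(sub) <- NULL
  sub <- structure(sub, class = c("circ_labels", "data.frame"))
  list(subset = sub, tpr = summarize_eval(sub)$tpr)
}
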