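# Per-circRNA properties and the S1/S2 contrast. True circRNAs (from the
# perfect-data evaluation) are split by whether a degraded ("imperfect")
# rerun still finds them: S1 = recovered, S2 = lost. Four properties are
# compared between the groups via empirical CDFs and the two-sample K-S test:
# splice-site distance, enrichment score E, junction reads ratio R and
# junction read count.

#' Junction reads ratio
#'
#' `R = n / N`, where `n` counts the reads supporting the back-splice junction
#' and `N` counts all reads (circular plus linear) around the circularised
#' region. `R` near 1 means the locus is mostly circular. Scale-invariant:
#' `R(cn, cN) = R(n, N)`. Vectorised.
#'
#' @param n Junction read count(s), `0 <= n <= N`.
#' @param N Total read count(s) around the region, `N > 0`.
#' @return `n / N` in `[0, 1]`.
#' @examples
#' junction_ratio(5, 20)   # 0.25
#' @export
junction_ratio <- function(n, N) {
  if (any(n < 0)) stop_("n must be non-negative")
  if (any(N == 0)) stop_("junction ratio undefined for N == 0")
  if (any(n > N)) stop_("n cannot exceed N")
  n / N
}

#' Distance between back-splice sites
#'
#' The 1-based inclusive span `end - start + 1` of a candidate.
#'
#' @param start,end Back-splice sites (1-based inclusive), or pass a
#'   [prediction_set] / `circ_labels` data frame as `start`.
#' @return Integer distance(s).
#' @examples
#' splice_distance(100, 200)   # 101
#' @export
splice_distance <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  if (any(start > end)) stop_("start must be <= end")
  as.integer(end) - as.integer(start) + 1L
}

#' Split true circRNAs into recovered (S1) and lost (S2) groups
#'
#' Partitions the true circRNAs from the perfect-data evaluation by presence
#' in a prediction set obtained from degraded data (after the usual junction
#' read filter). The two groups are disjoint and exhaustive.
#'
#' @param true_circs A `circ_labels` data frame; rows with `is_true == FALSE`
#'   are dropped with a warning.
#' @param imperfect_preds A [prediction_set] from the degraded data.
#' @param min_reads Junction read filter applied to `imperfect_preds`.
#' @return A list with character key vectors `S1` (recovered) and `S2` (lost).
#' @export
split_groups <- function(true_circs, imperfect_preds, min_reads = 2L) {
  if (!all(true_circs$is_true)) {
    warning("dropping candidates with is_true == FALSE", call. = FALSE)
    true_circs <- true_circs[true_circs$is_true, , drop = FALSE]
  }
  imperfect_preds <- filter_min_junction_reads(imperfect_preds, min_reads)
  true_keys <- candidate_key(true_circs$chrom, true_circs$start, true_circs$end)
  imp_keys <- candidate_key(imperfect_preds$chrom, imperfect_preds$start,
                            imperfect_preds$end)
  found <- true_keys %in% imp_keys
  list(S1 = true_keys[found], S2 = true_keys[!found])
}

#' Property table for labelled candidates
#'
#' One row per candidate with the four comparison properties: `distance`
#' (splice-site span), `E` (enrichment score), `R` (junction reads ratio
#' `n / region_reads`, `NA` when no region read count is available) and
#' `reads` (total-RNA junction read count `n` — the quantity available at
#' prediction time).
#'
#' @param labeled A `circ_labels` data frame.
#' @return A data frame keyed by `key` with columns `distance`, `E`, `R`,
#'   `reads`.
#' @export
property_table <- function(labeled) {
  R <- ifelse(!is.na(labeled$region_reads) & labeled$region_reads > 0,
              labeled$n / labeled$region_reads, NA_real_)
  data.frame(
    key = candidate_key(labeled$chrom, labeled$start, labeled$end),
    distance = splice_distance(labeled$start, labeled$end),
    E = labeled$E,
    R = R,
    reads = labeled$n,
    stringsAsFactors = FALSE
  )
}

#' Compare property distributions between S1 and S2
#'
#' Runs the two-sample K-S test per property between the recovered (S1) and
#' lost (S2) groups. `shift_direction == "right"` means the S1 distribution
#' sits higher. A property that is entirely `NA` in either group (e.g. `R`
#' without region read counts) is skipped.
#'
#' @param props A property table from [property_table()].
#' @param groups A list with key vectors `S1` and `S2` from [split_groups()].
#' @return A data frame with one row per property: `property`, `n_S1`, `n_S2`,
#'   `D`, `p_value`, `shift_direction`.
#' @export
compare_properties <- function(props, groups) {
  if (!length(groups$S1) || !length(groups$S2))
    stop_("both groups must be non-empty; skip the comparison otherwise")
  s1 <- props[props$key %in% groups$S1, , drop = FALSE]
  s2 <- props[props$key %in% groups$S2, , drop = FALSE]
  rows <- lapply(c("distance", "E", "R", "reads"), function(p) {
    x <- s1[[p]][!is.na(s1[[p]])]
    y <- s2[[p]][!is.na(s2[[p]])]
    if (!length(x) || !length(y)) return(NULL)
    k <- ks_two_sample(x, y)
    data.frame(property = p, n_S1 = k$n1, n_S2 = k$n2, D = k$D,
               p_value = k$p_value, shift_direction = k$shift_direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot S1 vs S2 property CDFs
#'
#' One panel per property, red = S1 (recovered), green = S2 (lost); read-count
#' style properties are drawn on a log axis when all values are positive.
#'
#' @param props A property table from [property_table()].
#' @param groups A list with key vectors `S1` and `S2`.
#' @param properties Which property columns to draw.
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plot_property_cdfs <- function(props, groups,
                               properties = c("distance", "E", "R", "reads")) {
  s1 <- props[props$key %in% groups$S1, , drop = FALSE]
  s2 <- props[props$key %in% groups$S2, , drop = FALSE]
  properties <- properties[vapply(properties, function(p) {
    any(!is.na(s1[[p]])) && any(!is.na(s2[[p]]))
  }, logical(1L))]
  old <- graphics::par(mfrow = c(1, length(properties)))
  on.exit(graphics::par(old))
  for (p in properties) {
    x <- s1[[p]][!is.na(s1[[p]])]
    y <- s2[[p]][!is.na(s2[[p]])]
    log_axis <- p %in% c("distance", "reads") && min(c(x, y)) > 0
    e1 <- ecdf_step(x); e2 <- ecdf_step(y)
    xlim <- range(c(x, y))
    graphics::plot(NA, xlim = xlim, ylim = c(0, 1), xlab = p, ylab = "CDF",
                   main = p, log = if (log_axis) "x" else "")
    graphics::lines(stats::stepfun(e1$x, c(0, e1$F)), col = "red",
                    do.points = FALSE)
    graphics::lines(stats::stepfun(e2$x, c(0, e2$F)), col = "green",
                    do.points = FALSE)
    graphics::legend("bottomright", legend = c("S1", "S2"),
                     col = c("red", "green"), lty = 1, bty = "n")
  }
  invisible(NULL)
}
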