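# End-to-end orchestration: simulate -> degrade -> predict -> evaluate ->
# properties. Every output is a pure function of (config, seed): each stage
# draws from a stream derived from the global seed and a stage label.

#' Configure a benchmark pipeline run
#'
#' Either a fully synthetic run (the default: reads are simulated from
#' `sim`, degraded, predicted and evaluated) or an evaluation-only run on
#' externally produced prediction tables (`total_preds` / `rnaser_preds`
#' given; simulate/degrade/predict stages are skipped).
#'
#' @param sim A [sim_config] for the synthetic stages.
#' @param min_reads Junction read filter applied to every prediction set.
#' @param subsample_rates Depth titration rates for the degradation grid.
#' @param error_ks Per-read substitution counts for the degradation grid. All
#'   error conditions share one derived seed, so their mutated position sets
#'   are nested across k.
#' @param top_k Size of the read-count re-ranked subset.
#' @param properties_conditions Degradation condition labels on which the
#'   S1/S2 property comparison is run.
#' @param total_preds,rnaser_preds Optional [prediction_set]s (or paths to
#'   BED-like tables) for an evaluation-only run.
#' @param seed Global seed; defaults to `sim$seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       min_reads = 2L,
                       subsample_rates = c(0.8, 0.5, 0.2),
                       error_ks = c(2L, 5L, 10L, 20L),
                       top_k = 25L,
                       properties_conditions = c("single_end_1",
                                                 "subsample_0.5", "errors_5"),
                       total_preds = NULL, rnaser_preds = NULL,
                       seed = NULL) {
  if (xor(is.null(total_preds), is.null(rnaser_preds)))
    stop_("evaluation-only runs need both total_preds and rnaser_preds")
  structure(list(
    sim = sim, min_reads = as.integer(min_reads),
    subsample_rates = subsample_rates, error_ks = as.integer(error_ks),
    top_k = as.integer(top_k),
    properties_conditions = properties_conditions,
    total_preds = total_preds, rnaser_preds = rnaser_preds,
    seed = as.integer(seed %||% sim$seed)
  ), class = "run_config")
}

as_prediction_set <- function(x, what) {
  if (inherits(x, "prediction_set")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(parse_prediction_table(x, "bedlike"))
  stop_("%s must be a prediction_set or a path to a bedlike table", what)
}

#' Evaluate a total-RNA prediction set against an RNase R run
#'
#' The real-data entry point: filters both sets, labels every total-RNA
#' candidate by its enrichment score and summarises the true positive rate.
#'
#' @param total,rnaser [prediction_set]s (or paths to BED-like tables).
#' @param min_reads Junction read filter.
#' @return A list with `labeled` (a `circ_labels` data frame) and `summary`
#'   (a `circ_eval`).
#' @export
evaluate_predictions <- function(total, rnaser, min_reads = 2L) {
  total <- filter_min_junction_reads(as_prediction_set(total, "total"),
                                     min_reads)
  rnaser <- filter_min_junction_reads(as_prediction_set(rnaser, "rnaser"),
                                      min_reads)
  labeled <- label_candidates(total, rnaser)
  list(labeled = labeled, summary = summarize_eval(labeled))
}

condition_row <- function(label, labeled, planted_keys, true_keys) {
  key <- candidate_key(labeled$chrom, labeled$start, labeled$end)
  data.frame(
    condition = label,
    n_predicted = nrow(labeled),
    n_overlap_with_rnaser = sum(labeled$m > 0),
    n_true = sum(labeled$is_true),
    tpr_percent = summarize_eval(labeled)$tpr_percent,
    n_detected_planted = sum(key %in% planted_keys),
    n_true_planted = sum(labeled$is_true & key %in% planted_keys),
    n_recovered_true = sum(key %in% true_keys),
    stringsAsFactors = FALSE)
}

#' Run the full benchmark pipeline
#'
#' Synthetic mode: simulates the transcriptome and both libraries, predicts
#' with the anchor pseudo-predictor, labels total-RNA candidates against the
#' RNase-R run, then re-predicts under every degradation condition (single-end
#' projections, depth titration, error injection), labelling each against the
#' same RNase-R prediction set — one evaluation row per condition. The S1/S2
#' property comparison (K-S tables) is run on the configured conditions, and
#' the read-count re-ranking on the full labelled set. Rerunning with the same
#' config reproduces identical results.
#'
#' Evaluation-only mode (external `total_preds`/`rnaser_preds` in the config):
#' only the labelling, summary and re-ranking stages run.
#'
#' @param config A [run_config].
#' @param out_dir Optional directory; when given, writes `summary.json`,
#'   `labeled.tsv` and one `ks_<condition>.tsv` per property comparison.
#' @return A list of class `circbench_run`: `summary` (overall `circ_eval`),
#'   `conditions` (per-condition evaluation table), `labeled`, `ks_tables`,
#'   `top_k`, plus (synthetic mode) `tx` and the full/treated prediction sets.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  external <- !is.null(config$total_preds)

  if (external) {
    ev <- evaluate_predictions(config$total_preds, config$rnaser_preds,
                               config$min_reads)
    run <- list(config = config, summary = ev$summary, labeled = ev$labeled,
                conditions = NULL, ks_tables = list(),
                top_k = top_k_by_reads(ev$labeled, config$top_k))
    class(run) <- "circbench_run"
    if (!is.null(out_dir)) write_run(run, out_dir)
    return(run)
  }

  sim_cfg <- config$sim
  seed <- config$seed
  tx <- simulate_transcriptome(sim_cfg)
  total <- simulate_reads(tx, sim_cfg, "total",
                          seed = derive_seed(seed, "reads_total"))
  rnaser <- simulate_reads(tx, sim_cfg, "rnaser",
                           seed = derive_seed(seed, "reads_rnaser"))
  preds_total <- filter_min_junction_reads(
    region_read_counts(pseudo_predict(total$pairs, tx, sim_cfg, "sim_total"),
                       total$truth),
    config$min_reads)
  preds_rnaser <- filter_min_junction_reads(
    pseudo_predict(rnaser$pairs, tx, sim_cfg, "sim_rnaser"),
    config$min_reads)
  labeled <- label_candidates(preds_total, preds_rnaser)
  overall <- summarize_eval(labeled)
  true_set <- labeled[labeled$is_true, , drop = FALSE]
  true_keys <- candidate_key(true_set$chrom, true_set$start, true_set$end)

  # degradation grid; the errors conditions share one seed (nested damage)
  degraded_reads <- c(
    list(single_end_1 = split_single_end(total$pairs, 1L),
         single_end_2 = split_single_end(total$pairs, 2L)),
    stats::setNames(lapply(config$subsample_rates, function(r)
      subsample_pairs(total$pairs, r,
                      derive_seed(seed, sprintf("subsample_%g", r)))),
      sprintf("subsample_%g", config$subsample_rates)),
    stats::setNames(lapply(config$error_ks, function(k)
      inject_errors(total$pairs, k, derive_seed(seed, "errors"))),
      sprintf("errors_%d", config$error_ks))
  )
  cond_preds <- lapply(degraded_reads, function(rd)
    filter_min_junction_reads(pseudo_predict(rd, tx, sim_cfg),
                              config$min_reads))
  cond_labeled <- lapply(cond_preds, label_candidates, rnaser = preds_rnaser)

  planted_keys <- tx$circs$key
  conditions <- rbind(
    condition_row("full", labeled, planted_keys, true_keys),
    do.call(rbind, lapply(names(cond_labeled), function(nm)
      condition_row(nm, cond_labeled[[nm]], planted_keys, true_keys))))
  rownames(conditions) <- NULL

  props <- property_table(true_set)
  ks_tables <- list()
  groups <- list()
  for (nm in intersect(config$properties_conditions, names(cond_preds))) {
    g <- split_groups(true_set, cond_preds[[nm]], config$min_reads)
    groups[[nm]] <- g
    if (length(g$S1) && length(g$S2))
      ks_tables[[nm]] <- compare_properties(props, g)
  }

  run <- list(config = config, tx = tx, summary = overall, labeled = labeled,
              conditions = conditions, ks_tables = ks_tables, groups = groups,
              properties = props,
              top_k = top_k_by_reads(labeled, config$top_k),
              preds_total = preds_total, preds_rnaser = preds_rnaser,
              cond_preds = cond_preds)
  class(run) <- "circbench_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- run$summary
  out <- list(
    seed = run$config$seed,
    overall = list(n_predicted = s$n_predicted,
                   n_overlap_with_rnaser = s$n_overlap_with_rnaser,
                   n_true = s$n_true, tpr = s$tpr,
                   tpr_percent = s$tpr_percent),
    conditions = run$conditions,
    top_k = list(k = run$config$top_k, tpr = run$top_k$tpr),
    ks = run$ks_tables)
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.table(run$labeled, file.path(out_dir, "labeled.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(run$ks_tables))
    utils::write.table(run$ks_tables[[nm]],
                       file.path(out_dir, sprintf("ks_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.circbench_run <- function(x, ...) {
  cat("<circbench_run>\n")
  print(x$summary)
  if (!is.null(x$conditions)) {
    cat("\nDegradation conditions:\n")
    print(x$conditions, row.names = FALSE)
  }
  if (length(x$ks_tables)) {
    for (nm in names(x$ks_tables)) {
      cat(sprintf("\nS1/S2 property comparison (%s):\n", nm))
      print(x$ks_tables[[nm]], row.names = FALSE)
    }
  }
  if (!is.null(x$top_k))
    cat(sprintf("\nTop-%d by read count: TPR %.2f%%\n", x$config$top_k,
                100 * x$top_k$tpr))
  invisible(x)
}
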