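# Fully synthetic, ground-truthed stand-in for a total-RNA / RNase-R library
# pair: a toy transcriptome with planted circular transcripts (plus linear
# transcripts, host transcripts overlapping the circles, and decoy loci that
# emulate caller false positives), paired-end read simulation from both
# treatments, and an anchor-based back-splice-junction pseudo-predictor.
#
# The pseudo-predictor searches only the planted junction probes (it evaluates
# the EVALUATION framework, not de-novo circRNA calling): a read supports a
# junction if it contains the 2*min_overlap-wide probe core — min_overlap
# bases on each side of the junction point — with at most max_mismatch
# mismatches, on either strand.

#' Configuration for the synthetic benchmark
#'
#' Defaults define the package's reference study conditions: 50 planted
#' circRNAs and 100 linear transcripts on a 500 kb toy chromosome, 100 bp
#' paired-end reads, 200,000 pairs for the total-RNA library.
#'
#' CircRNA abundance is parameterised in interpretable units: the expected
#' number of BSJ-spanning read pairs per circRNA at `depth` follows a
#' truncated Pareto (Zipf-like, shape `circ_cov_alpha`) law with median
#' `circ_cov_median` and cap `circ_cov_cap`. The default median of 2 puts most
#' planted circles near the 2-read detection threshold — circRNAs are one to
#' two orders of magnitude rarer than their host mRNAs, and junction coverage
#' near the threshold is what makes prediction sensitive to depth, exactly the
#' regime the degradation experiments probe. Internal expression weights are
#' derived from this target against the realised linear background.
#'
#' RNase R treatment retains each linear-derived fragment with probability
#' `rnaser_linear_survival` and each circ-derived fragment with
#' `rnaser_circ_survival`; the treated library draws
#' `depth * rnaser_depth_factor` fragments before depletion, because a
#' digested pool is still sequenced at full instrument depth, not at a
#' fraction of it. The depletion efficiency (default survival 0.05) is a free
#' parameter of the model — no measured value exists for it.
#'
#' @param n_circ Number of planted circRNAs.
#' @param n_linear Number of background linear transcripts.
#' @param n_decoys Number of decoy junction loci (false-positive channel):
#'   junction keys whose probe is ordinary linear sequence from a dedicated
#'   low-expression host, so they attract reads by coverage, not circularity.
#' @param host_prob Probability that a circRNA lies inside an expressed linear
#'   host transcript (source of linear reads around the junction, hence of
#'   junction-ratio denominators).
#' @param genome_length,chrom Toy chromosome size and name.
#' @param read_length Read length in bp (100, matching 100-bp paired-end data).
#' @param fragment_mean,fragment_sd Fragment length model, truncated to
#'   `[read_length, transcript length]`.
#' @param depth Total-RNA library size in read pairs.
#' @param linear_meanlog,linear_sdlog Log-normal expression weights of linear
#'   (and host) transcripts.
#' @param linear_len_meanlog,linear_len_sdlog,linear_len_range Linear
#'   transcript length model (log-normal, clamped).
#' @param circ_len_meanlog,circ_len_sdlog,circ_len_range CircRNA span model;
#'   the lower bound must be at least `2 * read_length` so a read can span the
#'   junction with flanks. Spans are drawn independently of expression.
#' @param circ_cov_median,circ_cov_cap,circ_cov_alpha Truncated-Pareto model
#'   of expected BSJ-spanning pairs per circRNA at `depth` (see Details).
#' @param decoy_cov_scale Decoy coverage relative to the circRNA law; below 1,
#'   false-positive candidates carry systematically fewer reads, as spurious
#'   calls do.
#' @param host_ext_range Range (bp) by which a host transcript extends beyond
#'   its circRNA on each side.
#' @param rnaser_linear_survival,rnaser_circ_survival Per-fragment retention
#'   probabilities under RNase R.
#' @param rnaser_depth_factor Fragments drawn for the treated library,
#'   relative to `depth`.
#' @param junction_flank Bases kept on each side of a junction when building
#'   probes.
#' @param min_overlap Minimum bases required on each side of the junction
#'   point for a read to support it.
#' @param max_mismatch Mismatches tolerated across the probe core.
#' @param seed Integer seed; every stage derives its own stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_circ = 50L, n_linear = 100L, n_decoys = 25L,
                       host_prob = 0.8,
                       genome_length = 500000L, chrom = "chr1",
                       read_length = 100L,
                       fragment_mean = 250, fragment_sd = 50,
                       depth = 200000L,
                       linear_meanlog = 0, linear_sdlog = 1,
                       linear_len_meanlog = log(1200), linear_len_sdlog = 0.4,
                       linear_len_range = c(400L, 4000L),
                       circ_len_meanlog = log(800), circ_len_sdlog = 0.5,
                       circ_len_range = c(300L, 3000L),
                       circ_cov_median = 2, circ_cov_cap = 25,
                       circ_cov_alpha = 1,
                       decoy_cov_scale = 0.5,
                       host_ext_range = c(200L, 800L),
                       rnaser_linear_survival = 0.05,
                       rnaser_circ_survival = 1.0,
                       rnaser_depth_factor = 5,
                       junction_flank = 20L, min_overlap = 10L,
                       max_mismatch = 2L,
                       seed = 101L) {
  cfg <- as.list(environment())
  if (cfg$depth <= 0) stop_("depth must be positive")
  for (p in c("rnaser_linear_survival", "rnaser_circ_survival"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_("%s must be in [0, 1]", p)
  if (cfg$circ_len_range[1L] < 2L * cfg$read_length)
    stop_("circ_len_range lower bound must be >= 2 * read_length")
  if (cfg$min_overlap > cfg$junction_flank)
    stop_("min_overlap cannot exceed junction_flank")
  if (cfg$fragment_mean < cfg$read_length)
    stop_("fragment_mean must be >= read_length")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d circ / %d linear / %d decoys on %s (%d bp)\n",
    "  %d bp paired reads, %s pairs; RNase R survival lin %.2f / circ %.2f,",
    " depth factor %g; seed %d\n"),
    x$n_circ, x$n_linear, x$n_decoys, x$chrom, x$genome_length,
    x$read_length, format(x$depth, big.mark = ","),
    x$rnaser_linear_survival, x$rnaser_circ_survival, x$rnaser_depth_factor,
    x$seed))
  invisible(x)
}

rlnorm_clamped <- function(n, meanlog, sdlog, range) {
  as.integer(pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)),
                       range[1L]), range[2L]))
}

# truncated Pareto draw: median `med`, shape `alpha`, cap `cap`
rpareto_trunc <- function(n, med, alpha, cap) {
  xm <- med / 2^(1 / alpha)
  pmin(xm / stats::runif(n)^(1 / alpha), cap)
}

random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# per-mate window of fragment start positions whose read spans the junction
# with >= min_overlap bases on each side; both mates together (disjoint
# windows for typical fragment lengths)
span_windows <- function(config) {
  2L * (config$read_length - 2L * config$min_overlap + 1L)
}

#' Simulate a toy transcriptome with planted circRNAs
#'
#' Lays out, without overlap between loci: `n_linear` background linear
#' transcripts; `n_circ` circRNA spans, each embedded (with probability
#' `host_prob`) in a linear host transcript extending beyond it; and
#' `n_decoys` decoy loci. Expression weights: linear/host log-normal; circRNA
#' and decoy weights derived from the configured junction-coverage law against
#' the realised linear background (the small circular fraction itself is
#' neglected in the normalisation). Deterministic given `config$seed`.
#'
#' @param config A [sim_config].
#' @return A list of class `synthetic_transcriptome`: `genome` (named
#'   character), `transcripts` (all read-producing transcripts), `circs`
#'   (planted keys with coverage targets), `decoys`, `config`.
#' @export
simulate_transcriptome <- function(config) {
  with_seed(derive_seed(config$seed, "transcriptome"), {
    n_c <- config$n_circ; n_l <- config$n_linear; n_d <- config$n_decoys
    lin_len <- rlnorm_clamped(n_l, config$linear_len_meanlog,
                              config$linear_len_sdlog, config$linear_len_range)
    circ_len <- rlnorm_clamped(n_c, config$circ_len_meanlog,
                               config$circ_len_sdlog, config$circ_len_range)
    decoy_len <- rlnorm_clamped(n_d, config$circ_len_meanlog,
                                config$circ_len_sdlog, config$circ_len_range)
    has_host <- stats::runif(n_c) < config$host_prob
    host_ext <- matrix(as.integer(round(stats::runif(
      2L * n_c, config$host_ext_range[1L], config$host_ext_range[2L]))),
      ncol = 2L)

    # locus widths: circ loci include their host extension
    circ_width <- ifelse(has_host, circ_len + host_ext[, 1L] + host_ext[, 2L],
                         circ_len)
    widths <- c(lin_len, circ_width, decoy_len)
    n_loci <- length(widths)
    gaps <- as.integer(round(stats::runif(n_loci, 100, 500)))
    order_ix <- sample.int(n_loci)
    total <- sum(widths) + sum(gaps)
    if (total > config$genome_length)
      stop_("chromosome too short: need %d bp, have %d", total,
            config$genome_length)
    starts_packed <- cumsum(c(1L, widths[order_ix] + gaps[order_ix]))
    locus_start <- integer(n_loci)
    locus_start[order_ix] <- starts_packed[seq_len(n_loci)]

    lin_start <- locus_start[seq_len(n_l)]
    circ_locus <- locus_start[n_l + seq_len(n_c)]
    decoy_start <- locus_start[n_l + n_c + seq_len(n_d)]

    circ_start <- circ_locus + ifelse(has_host, host_ext[, 1L], 0L)
    circ_end <- circ_start + circ_len - 1L

    lin_w <- stats::rlnorm(n_l, config$linear_meanlog, config$linear_sdlog)
    host_w <- stats::rlnorm(n_c, config$linear_meanlog, config$linear_sdlog)
    circ_cov <- rpareto_trunc(n_c, config$circ_cov_median,
                              config$circ_cov_alpha, config$circ_cov_cap)
    decoy_cov <- rpareto_trunc(n_d, config$decoy_cov_scale *
                               config$circ_cov_median,
                               config$circ_cov_alpha, config$circ_cov_cap)

    lin_df <- data.frame(
      tx_id = sprintf("lin%03d", seq_len(n_l)),
      type = rep("linear", n_l),
      start = lin_start, end = lin_start + lin_len - 1L,
      length = lin_len, weight = lin_w, stringsAsFactors = FALSE)
    host_df <- data.frame(
      tx_id = sprintf("host%03d", which(has_host)),
      type = rep("host", sum(has_host)),
      start = circ_locus[has_host],
      end = (circ_start + circ_len - 1L + host_ext[, 2L])[has_host],
      length = (circ_width)[has_host], weight = host_w[has_host],
      stringsAsFactors = FALSE)

    # expression weight per expected junction-covering pair, against the
    # linear background mass (circ + decoy mass is < 1% and neglected)
    s_bg <- sum(lin_df$weight * lin_df$length) +
      sum(host_df$weight * host_df$length)
    w_per_cov <- s_bg / (config$depth * span_windows(config))

    decoy_df <- data.frame(
      tx_id = sprintf("dhost%03d", seq_len(n_d)),
      type = rep("decoy_host", n_d),
      start = decoy_start, end = decoy_start + decoy_len - 1L,
      length = decoy_len, weight = decoy_cov * w_per_cov,
      stringsAsFactors = FALSE)
    circ_tx <- data.frame(
      tx_id = sprintf("circ%03d", seq_len(n_c)),
      type = rep("circ", n_c),
      start = circ_start, end = circ_end, length = circ_len,
      weight = circ_cov * w_per_cov, stringsAsFactors = FALSE)

    transcripts <- rbind(lin_df, host_df, decoy_df, circ_tx)
    transcripts$chrom <- rep(config$chrom, nrow(transcripts))
    transcripts$is_circ <- transcripts$type == "circ"

    circs <- data.frame(
      tx_id = circ_tx$tx_id, chrom = rep(config$chrom, n_c),
      start = circ_start, end = circ_end, length = circ_len,
      weight = circ_tx$weight, cov_target = circ_cov,
      host_id = ifelse(has_host, sprintf("host%03d", seq_len(n_c)),
                       NA_character_),
      key = candidate_key(rep(config$chrom, n_c), circ_start, circ_end),
      stringsAsFactors = FALSE)
    if (anyDuplicated(circs$key)) stop_("internal: duplicate planted keys")

    decoys <- data.frame(
      decoy_id = decoy_df$tx_id, chrom = rep(config$chrom, n_d),
      start = decoy_df$start, end = decoy_df$end,
      probe_point = decoy_df$start +
        as.integer(decoy_df$length %/% 2L),
      key = candidate_key(rep(config$chrom, n_d), decoy_df$start,
                          decoy_df$end),
      stringsAsFactors = FALSE)

    genome <- stats::setNames(random_genome(config$genome_length),
                              config$chrom)
    structure(list(genome = genome, transcripts = transcripts, circs = circs,
                   decoys = decoys, config = config),
              class = "synthetic_transcriptome")
  })
}

#' @export
print.synthetic_transcriptome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_transcriptome> %d transcripts (%d circ, %d decoy loci) on %s\n",
    nrow(x$transcripts), nrow(x$circs), nrow(x$decoys),
    names(x$genome)[1L]))
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a paired-end library from the toy transcriptome
#'
#' Fragments are drawn from transcripts proportional to expression weight
#' times length; fragment length is Normal(`fragment_mean`, `fragment_sd`)
#' truncated to `[read_length, transcript length]`; circular transcripts are
#' fragmented on the circle, so fragments may wrap the back-splice junction
#' and produce BSJ-spanning reads. Sequenced strand is uniform. Under
#' `treatment = "rnaser"`, `depth * rnaser_depth_factor` fragments are drawn
#' and each is retained with its class survival probability. Qualities are
#' constant `"I"` (no stage consumes quality values). Deterministic given the
#' seed.
#'
#' @param tx A [simulate_transcriptome()] result.
#' @param config A [sim_config] (defaults to the one inside `tx`).
#' @param treatment `"total"` or `"rnaser"`.
#' @param seed Stage seed; defaults to one derived from `config$seed` and the
#'   treatment.
#' @return A list with `pairs` (a [read_pairs]) and `truth` (per-pair
#'   provenance: source transcript, circ flag, per-mate BSJ-spanning flags,
#'   genomic mate intervals for linear-derived pairs).
#' @export
simulate_reads <- function(tx, config = tx$config,
                           treatment = c("total", "rnaser"), seed = NULL) {
  treatment <- match.arg(treatment)
  seed <- seed %||% derive_seed(config$seed, paste0("reads_", treatment))
  t_tab <- tx$transcripts
  L <- config$read_length
  with_seed(seed, {
    n_frag <- as.integer(round(config$depth *
      if (treatment == "rnaser") config$rnaser_depth_factor else 1))
    idx <- sample.int(nrow(t_tab), n_frag, replace = TRUE,
                      prob = t_tab$weight * t_tab$length)
    if (treatment == "rnaser") {
      surv <- ifelse(t_tab$is_circ[idx], config$rnaser_circ_survival,
                     config$rnaser_linear_survival)
      idx <- idx[stats::runif(n_frag) < surv]
    }
    n <- length(idx)
    len <- t_tab$length[idx]
    is_circ <- t_tab$is_circ[idx]
    flen <- pmin(pmax(as.integer(round(stats::rnorm(
      n, config$fragment_mean, config$fragment_sd))), L), len)
    u <- stats::runif(n)
    off <- 1L + as.integer(floor(u * ifelse(is_circ, len, len - flen + 1L)))
    flip <- stats::runif(n) < 0.5

    txseq_all <- substr(tx$genome[t_tab$chrom], t_tab$start, t_tab$end)
    txseq <- txseq_all[idx]
    frag_end <- off + flen - 1L
    over <- frag_end - len
    frag <- substr(txseq, off, frag_end)
    wrap <- is_circ & over > 0L
    if (any(wrap)) {
      frag[wrap] <- paste0(substr(txseq[wrap], off[wrap], len[wrap]),
                           substr(txseq[wrap], 1L, over[wrap]))
    }
    first_piece <- substr(frag, 1L, L)
    rc_last <- revcomp(substr(frag, flen - L + 1L, flen))
    mate1 <- ifelse(flip, rc_last, first_piece)
    mate2 <- ifelse(flip, first_piece, rc_last)

    ids <- sprintf("%s_%07d", treatment, seq_len(n))
    qual <- strrep("I", L)
    pairs <- read_pairs(
      fastq_records(ids, mate1, rep(qual, n), 1L),
      fastq_records(ids, mate2, rep(qual, n), 2L))

    # BSJ-spanning flags: 0-based circle position of each mate's first base
    # (coverage is orientation-independent); the junction sits between
    # positions len-1 and 0, spanned with >= min_overlap bases on each side
    mo <- config$min_overlap
    a1 <- (off - 1L) %% len
    a2 <- (off - 1L + flen - L) %% len
    spans1_f <- is_circ & a1 >= len - L + mo & a1 <= len - mo
    spans2_f <- is_circ & a2 >= len - L + mo & a2 <= len - mo
    # report per emitted mate (mate1 = fragment start unless flipped)
    spans1 <- ifelse(flip, spans2_f, spans1_f)
    spans2 <- ifelse(flip, spans1_f, spans2_f)

    g1s <- t_tab$start[idx] + off - 1L
    g2s <- g1s + flen - L
    truth <- data.frame(
      read_id = ids, tx_id = t_tab$tx_id[idx], is_circ = is_circ,
      spans1 = spans1, spans2 = spans2, spans_bsj = spans1 | spans2,
      chrom = t_tab$chrom[idx],
      m1_start = ifelse(is_circ, NA_integer_, ifelse(flip, g2s, g1s)),
      m1_end = ifelse(is_circ, NA_integer_, ifelse(flip, g2s, g1s) + L - 1L),
      m2_start = ifelse(is_circ, NA_integer_, ifelse(flip, g1s, g2s)),
      m2_end = ifelse(is_circ, NA_integer_, ifelse(flip, g1s, g2s) + L - 1L),
      stringsAsFactors = FALSE)
    list(pairs = pairs, truth = truth)
  })
}

probe_cores <- function(tx, config = tx$config) {
  J <- config$junction_flank
  mo <- config$min_overlap
  genome <- tx$genome[tx$circs$chrom]
  cseq <- substr(genome, tx$circs$start, tx$circs$end)
  clen <- nchar(cseq)
  probe <- paste0(substr(cseq, clen - J + 1L, clen), substr(cseq, 1L, J))
  circ_core <- substr(probe, J - mo + 1L, J + mo)
  dec_core <- substr(tx$genome[tx$decoys$chrom],
                     tx$decoys$probe_point - mo + 1L,
                     tx$decoys$probe_point + mo)
  data.frame(
    key = c(tx$circs$key, tx$decoys$key),
    chrom = c(tx$circs$chrom, tx$decoys$chrom),
    start = c(tx$circs$start, tx$decoys$start),
    end = c(tx$circs$end, tx$decoys$end),
    planted = rep(c(TRUE, FALSE), c(nrow(tx$circs), nrow(tx$decoys))),
    core = c(circ_core, dec_core),
    stringsAsFactors = FALSE)
}

#' Anchor-based back-splice junction pseudo-predictor
#'
#' Screens reads against the junction probe cores of every planted circRNA
#' and decoy locus: a read supports a junction if it contains the core
#' (`min_overlap` bases each side of the junction point) on either strand
#' with at most `max_mismatch` mismatches. `junction_reads` counts supporting
#' read pairs (either mate counts; a pair counts once). Junctions with no
#' support are omitted.
#'
#' @param reads A [read_pairs] object or a single [fastq_records] data frame.
#' @param tx A [simulate_transcriptome()] result (source of the probes).
#' @param config A [sim_config].
#' @param sample_id Label for the resulting [prediction_set].
#' @return A [prediction_set] (strand `"."`, source `"pseudo_predictor"`).
#' @export
pseudo_predict <- function(reads, tx, config = tx$config,
                           sample_id = "pseudo") {
  pc <- probe_cores(tx, config)
  if (is_read_pairs(reads)) {
    bases <- c(reads$mate1$bases, reads$mate2$bases)
    npair <- n_pairs(reads)
    pair_of <- function(i) ((i - 1L) %% npair) + 1L
  } else {
    bases <- reads$bases
    npair <- nrow(reads)
    pair_of <- identity
  }
  if (npair == 0L || nrow(pc) == 0L)
    return(prediction_set(source = "pseudo_predictor", sample_id = sample_id))
  cores <- c(pc$core, revcomp(pc$core))
  hits <- .match_probe_cores(bases, cores, as.integer(config$max_mismatch))
  ki <- ((hits$core - 1L) %% nrow(pc)) + 1L
  pid <- pair_of(hits$read)
  dup <- duplicated(paste(ki, pid))
  counts <- tabulate(ki[!dup], nbins = nrow(pc))
  found <- counts > 0L
  prediction_set(
    chrom = pc$chrom[found], start = pc$start[found], end = pc$end[found],
    strand = ".", junction_reads = counts[found],
    source = "pseudo_predictor", sample_id = sample_id)
}

#' Region read counts from read provenance
#'
#' Operationalises the junction-ratio denominator `N` for synthetic data: for
#' each candidate, `N` is its junction read count plus the number of
#' linear-derived pairs with a mate overlapping either back-splice site
#' (computed exactly from the simulation's per-read provenance).
#'
#' @param preds A [prediction_set].
#' @param truth A truth table from [simulate_reads()].
#' @return `preds` with its `region_reads` column filled in.
#' @export
region_read_counts <- function(preds, truth) {
  lin <- truth[!truth$is_circ, , drop = FALSE]
  covers <- function(s, e, p) !is.na(s) & s <= p & e >= p
  n_lin <- vapply(seq_len(nrow(preds)), function(i) {
    same <- lin$chrom == preds$chrom[i]
    hit <- same & (
      covers(lin$m1_start, lin$m1_end, preds$start[i]) |
      covers(lin$m1_start, lin$m1_end, preds$end[i])   |
      covers(lin$m2_start, lin$m2_end, preds$start[i]) |
      covers(lin$m2_start, lin$m2_end, preds$end[i]))
    sum(hit)
  }, integer(1L))
  preds$region_reads <- preds$junction_reads + n_lin
  preds
}

#' Generate and write a complete synthetic benchmark
#'
#' Runs the full generator at `config`: transcriptome, total-RNA and RNase-R
#' paired-end FASTQ, per-pair truth tables and pseudo-predictor prediction
#' tables for both treatments, plus a JSON manifest (files, seed, planted and
#' detected counts). Two runs with the same config are byte-identical.
#'
#' @param config A [sim_config].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
make_benchmark <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tx <- simulate_transcriptome(config)
  files <- list()
  counts <- list(n_circ_planted = nrow(tx$circs), n_decoys = nrow(tx$decoys))
  for (treatment in c("total", "rnaser")) {
    sim <- simulate_reads(tx, config, treatment)
    for (m in 1:2) {
      f <- file.path(out_dir, sprintf("%s_R%d.fastq", treatment, m))
      write_fastq(sim$pairs[[m]], f)
      files[[sprintf("%s_R%d", treatment, m)]] <- basename(f)
    }
    tf <- file.path(out_dir, sprintf("truth_%s.tsv", treatment))
    utils::write.table(sim$truth, tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[sprintf("truth_%s", treatment)]] <- basename(tf)
    preds <- pseudo_predict(sim$pairs, tx, config,
                            sample_id = paste0("sim_", treatment))
    preds <- region_read_counts(preds, sim$truth)
    pf <- file.path(out_dir, sprintf("preds_%s.tsv", treatment))
    write_prediction_table(preds, pf)
    files[[sprintf("preds_%s", treatment)]] <- basename(pf)
    counts[[sprintf("n_pairs_%s", treatment)]] <- n_pairs(sim$pairs)
    counts[[sprintf("n_candidates_%s", treatment)]] <- nrow(preds)
  }
  manifest <- list(seed = config$seed, files = files, counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
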