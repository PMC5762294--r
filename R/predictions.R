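# Normalised circRNA candidate tables. One canonical convention everywhere:
# coordinates are 1-based inclusive (the CIRI convention); BED-like files are
# 0-based half-open and are shifted at the I/O boundary only. Junction identity
# is the exact triple (chrom, start, end); strand is recorded but never used
# for matching, because strand conventions differ between callers.

#' Construct a normalised circRNA prediction set
#'
#' One row per unique back-splice junction `(chrom, start, end)` with its
#' supporting junction read count. Duplicate keys are merged by summing
#' `junction_reads` (and `region_reads`, when present), keeping the first-seen
#' strand; rows are sorted by key so the result is independent of input order.
#'
#' @param chrom Character chromosome names.
#' @param start,end Integer back-splice sites, 1-based inclusive, `start <= end`.
#' @param strand `"+"`, `"-"` or `"."`; recorded, ignored for matching.
#' @param junction_reads Non-negative integer junction-spanning read counts.
#' @param region_reads Optional non-negative integers: all reads (circular plus
#'   linear) around the circularised region, the denominator of the junction
#'   reads ratio. `NA` when unknown.
#' @param source Tag for the producing algorithm.
#' @param sample_id Sample label stored as an attribute.
#' @return A data frame of class `prediction_set`.
#' @examples
#' prediction_set("chr1", c(100, 100), c(200, 200), "+", c(2, 3))
#' @export
prediction_set <- function(chrom = character(), start = integer(),
                           end = integer(), strand = ".",
                           junction_reads = integer(), region_reads = NULL,
                           source = "unknown", sample_id = "") {
  n <- length(start)
  start <- as.integer(start); end <- as.integer(end)
  junction_reads <- as.integer(junction_reads)
  # scalar chrom / junction_reads recycle over the candidates
  chrom <- if (length(chrom) == 1L) rep_len(as.character(chrom), n)
           else as.character(chrom)
  if (length(junction_reads) == 1L)
    junction_reads <- rep_len(junction_reads, n)
  strand <- rep_len(as.character(strand), n)
  source <- rep_len(as.character(source), n)
  region_reads <- if (is.null(region_reads)) rep(NA_integer_, n) else
    rep_len(as.integer(region_reads), n)
  if (length(chrom) != n || length(end) != n || length(junction_reads) != n)
    stop_("chrom, start, end and junction_reads must have equal length")
  if (any(start > end)) stop_("start > end for %d candidate(s)", sum(start > end))
  if (any(junction_reads < 0)) stop_("junction_reads must be non-negative")
  if (!all(strand %in% c("+", "-", "."))) stop_("strand must be +, - or .")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = strand, junction_reads = junction_reads,
                   region_reads = region_reads, source = source,
                   stringsAsFactors = FALSE)
  key <- candidate_key(df$chrom, df$start, df$end)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    agg_j <- rowsum(df$junction_reads, key, reorder = FALSE)
    agg_r <- rowsum(ifelse(is.na(df$region_reads), 0L, df$region_reads), key,
                    reorder = FALSE)
    any_r <- rowsum(as.integer(!is.na(df$region_reads)), key, reorder = FALSE)
    df <- df[first, , drop = FALSE]
    o <- match(candidate_key(df$chrom, df$start, df$end), rownames(agg_j))
    df$junction_reads <- as.integer(agg_j[o, 1L])
    df$region_reads <- ifelse(any_r[o, 1L] > 0L, as.integer(agg_r[o, 1L]),
                              NA_integer_)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("prediction_set", "data.frame"),
            sample_id = sample_id)
}

#' Canonical junction key
#'
#' @param chrom,start,end Candidate coordinates (1-based inclusive).
#' @return `"chrom:start-end"` strings used for all cross-sample matching.
#' @export
candidate_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d candidates, sample '%s'\n",
              nrow(x), attr(x, "sample_id") %||% ""))
  NextMethod()
}

as_int_checked <- function(x, what, line) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !(is.na(x) | x %in% c("NA", ".")))
  if (length(bad))
    stop_("line %d: non-integer %s '%s'", line[bad[1L]], what, x[bad[1L]])
  v
}

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

parse_bedlike <- function(path, source, sample_id) {
  lines <- read_tsv_lines(path)
  if (!length(lines))
    return(prediction_set(source = source, sample_id = sample_id))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 5L))
    stop_("line %d: expected >= 5 tab-separated fields", which(ncol < 5L)[1L])
  ln <- seq_along(lines)
  get <- function(i) vapply(f, `[[`, "", i)
  start0 <- as_int_checked(get(2L), "start", ln)
  prediction_set(
    chrom = get(1L),
    start = start0 + 1L,   # 0-based half-open -> 1-based inclusive
    end = as_int_checked(get(3L), "end", ln),
    strand = get(4L),
    junction_reads = as_int_checked(get(5L), "count", ln),
    region_reads = if (all(ncol >= 6L)) as_int_checked(get(6L), "region_reads", ln),
    source = source, sample_id = sample_id
  )
}

match_col <- function(header, candidates) {
  for (cand in candidates) {
    i <- which(tolower(header) == tolower(cand))
    if (length(i)) return(i[1L])
  }
  NA_integer_
}

parse_ciri <- function(path, source, sample_id) {
  lines <- read_tsv_lines(path)
  if (!length(lines) || !grepl("^circRNA_ID", lines[1L]))
    stop_("not a CIRI table: missing 'circRNA_ID' header in %s", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ic <- match_col(header, c("chr", "chrom"))
  is <- match_col(header, c("circRNA_start", "start"))
  ie <- match_col(header, c("circRNA_end", "end"))
  ij <- match_col(header, c("#junction_reads", "junction_reads"))
  istr <- match_col(header, "strand")
  if (anyNA(c(ic, is, ie, ij)))
    stop_("CIRI header lacks chr/start/end/#junction_reads columns")
  if (length(lines) == 1L)
    return(prediction_set(source = source, sample_id = sample_id))
  f <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ln <- seq_along(f) + 1L
  get <- function(i) vapply(f, `[[`, "", i)
  prediction_set(
    chrom = get(ic),
    start = as_int_checked(get(is), "start", ln),
    end = as_int_checked(get(ie), "end", ln),
    strand = if (!is.na(istr)) get(istr) else ".",
    junction_reads = as_int_checked(get(ij), "count", ln),
    source = source, sample_id = sample_id
  )
}

# KNIFE junction ids look like chrom|gene1:pos1|gene2:pos2|type|strand;
# minimally chrom|pos1|pos2. Positions are taken from the part after the last
# ':' within each field; the junction is normalised so start <= end.
parse_knife <- function(path, source, sample_id) {
  lines <- read_tsv_lines(path)
  if (!length(lines))
    return(prediction_set(source = source, sample_id = sample_id))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 2L))
    stop_("line %d: expected junction id and read count columns",
          which(lengths(f) < 2L)[1L])
  counts_raw <- vapply(f, `[[`, "", 2L)
  # tolerate a single header line
  if (is.na(suppressWarnings(as.integer(counts_raw[1L])))) {
    f <- f[-1L]; counts_raw <- counts_raw[-1L]
    if (!length(f)) return(prediction_set(source = source, sample_id = sample_id))
  }
  ln <- seq_along(f)
  parts <- strsplit(vapply(f, `[[`, "", 1L), "|", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop_("line %d: junction id is not 'chrom|pos1|pos2[|...]'",
          which(lengths(parts) < 3L)[1L])
  last_field <- function(x) sub(".*:", "", x)
  p1 <- as_int_checked(last_field(vapply(parts, `[[`, "", 2L)), "pos1", ln)
  p2 <- as_int_checked(last_field(vapply(parts, `[[`, "", 3L)), "pos2", ln)
  strand <- vapply(parts, function(p) {
    s <- intersect(p, c("+", "-", "rev", "fwd"))
    if (!length(s)) "." else switch(s[1L], rev = "-", fwd = "+", s[1L])
  }, "")
  prediction_set(
    chrom = vapply(parts, `[[`, "", 1L),
    start = pmin(p1, p2), end = pmax(p1, p2), strand = strand,
    junction_reads = as_int_checked(counts_raw, "count", ln),
    source = source, sample_id = sample_id
  )
}

#' Parse a circRNA prediction table
#'
#' Normalises the outputs of external circRNA callers to one canonical
#' candidate record. Three dialects are supported: `"ciri"` (headered TSV with
#' `chr`, `circRNA_start`, `circRNA_end`, `#junction_reads` columns, 1-based
#' inclusive), `"knife"` (junction id `chrom|pos1|pos2[|...]` plus a read-count
#' column, 1-based inclusive) and `"bedlike"` (headerless TSV `chrom, start0,
#' end, strand, junction_reads[, region_reads]`, 0-based half-open — the
#' package's own output format). Duplicate junction keys are merged by summing
#' counts.
#'
#' @param path Path to the table.
#' @param dialect One of `"bedlike"`, `"ciri"`, `"knife"`.
#' @param source Algorithm tag stored on the candidates; defaults to the dialect.
#' @param sample_id Sample label.
#' @return A [prediction_set].
#' @export
parse_prediction_table <- function(path,
                                   dialect = c("bedlike", "ciri", "knife"),
                                   source = NULL, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("no such file: %s", path)
  source <- source %||% dialect
  sample_id <- sample_id %||% tools::file_path_sans_ext(basename(path))
  switch(dialect,
    bedlike = parse_bedlike(path, source, sample_id),
    ciri = parse_ciri(path, source, sample_id),
    knife = parse_knife(path, source, sample_id)
  )
}

#' Write a prediction set as a BED-like table
#'
#' The canonical pipeline output dialect: headerless TSV with columns `chrom,
#' start0, end, strand, junction_reads` plus `region_reads` when any candidate
#' carries one. Start is converted to 0-based half-open on the way out.
#'
#' @param preds A [prediction_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(preds, path) {
  cols <- list(preds$chrom, preds$start - 1L, preds$end, preds$strand,
               preds$junction_reads)
  if (any(!is.na(preds$region_reads))) cols <- c(cols, list(preds$region_reads))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
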