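# FASTQ I/O. Hand-rolled 4-line reader/writer: the degradation simulators must
# round-trip records byte-identically (ids, qualities, order), which rules out
# readers that re-interpret or re-wrap records.

FASTQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a set of FASTQ records
#'
#' The in-memory representation of sequencing reads used throughout the
#' package: a data frame with one row per read and columns `read_id`, `mate`,
#' `bases`, `qualities`. Bases are restricted to `A,C,G,T,N`; the quality
#' string (Phred+33) must have the same length as the bases.
#'
#' @param read_id Character vector of read identifiers (without the `@`).
#' @param bases Character vector of base strings over `A,C,G,T,N`.
#' @param qualities Character vector of Phred+33 quality strings, same
#'   lengths as `bases`. Defaults to constant `"I"` (Q40).
#' @param mate Integer, 1 or 2, recycled.
#' @return A data frame of class `fastq_records`.
#' @examples
#' fastq_records("r1", "ACGT")
#' @export
fastq_records <- function(read_id, bases, qualities = NULL, mate = 1L) {
  read_id <- as.character(read_id)
  bases <- as.character(bases)
  if (is.null(qualities)) qualities <- strrep("I", nchar(bases))
  qualities <- as.character(qualities)
  mate <- rep_len(as.integer(mate), length(read_id))
  if (length(bases) != length(read_id) || length(qualities) != length(read_id))
    stop_("read_id, bases and qualities must have equal length")
  bad <- which(nchar(bases) != nchar(qualities))
  if (length(bad))
    stop_("record %d: sequence and quality lengths differ", bad[1L])
  if (any(grepl(sprintf("[^%s]", paste(FASTQ_ALPHABET, collapse = "")), bases)))
    stop_("bases contain characters outside {A,C,G,T,N}")
  if (!all(mate %in% c(1L, 2L))) stop_("mate must be 1 or 2")
  structure(
    data.frame(read_id = read_id, mate = mate, bases = bases,
               qualities = qualities, stringsAsFactors = FALSE),
    class = c("fastq_records", "data.frame")
  )
}

# gzip magic bytes 1f 8b
is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ, plain or gzip-compressed (compression is auto-detected
#' from the file's magic bytes, not its extension).
#'
#' @param path Path to a FASTQ file.
#' @param mate Mate number (1 or 2) to stamp on the records.
#' @return A [fastq_records] data frame, in file order.
#' @export
read_fastq <- function(path, mate = 1L) {
  if (!file.exists(path)) stop_("no such file: %s", path)
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L)
    return(fastq_records(character(), character(), character(), mate))
  if (length(lines) %% 4L != 0L)
    stop_("truncated FASTQ: %d lines is not a multiple of 4", length(lines))
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) stop_("record %d: header does not start with '@'", bad[1L])
  plus <- lines[idx + 2L]
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) stop_("record %d: separator line does not start with '+'", bad[1L])
  bases <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad <- which(nchar(bases) != nchar(quals))
  if (length(bad))
    stop_("record %d: sequence and quality lengths differ", bad[1L])
  fastq_records(sub("^@", "", hdr), bases, quals, mate)
}

#' Write FASTQ records
#'
#' Inverse of [read_fastq()]: `read_fastq(write_fastq(x, f))` reproduces `x`
#' exactly (ids, bases, qualities, order). Output is gzip-compressed when
#' `path` ends in `.gz`.
#'
#' @param records A [fastq_records] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(records)) {
    out <- rbind(paste0("@", records$read_id), records$bases, "+",
                 records$qualities)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

# strip an optional trailing /1 or /2 so mate files with suffixed ids pair up
pair_id <- function(id) sub("/[12]$", "", id)

#' Pair two mate FASTQ record sets
#'
#' Validates that the two mate files have equal record counts and matching
#' identifiers in order (a trailing `/1` / `/2` is ignored for the
#' comparison).
#'
#' @param mate1,mate2 [fastq_records] data frames for mates 1 and 2.
#' @return A list of class `read_pairs` with elements `mate1` and `mate2`.
#' @export
read_pairs <- function(mate1, mate2) {
  if (nrow(mate1) != nrow(mate2))
    stop_("mate files differ in record count (%d vs %d)",
          nrow(mate1), nrow(mate2))
  if (!identical(pair_id(mate1$read_id), pair_id(mate2$read_id)))
    stop_("mate read ids do not match in order")
  structure(list(mate1 = mate1, mate2 = mate2), class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("<read_pairs> %d pairs\n", nrow(x$mate1)))
  invisible(x)
}

n_pairs <- function(pairs) nrow(pairs$mate1)

is_read_pairs <- function(x) inherits(x, "read_pairs")
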