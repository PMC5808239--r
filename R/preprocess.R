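#' Read a FASTQ file tolerantly
#'
#' Parses 4-line-per-record FASTQ (optionally gzip-compressed). Malformed
#' records (missing `@`/`+` marker lines, quality string whose length does not
#' match the sequence, empty sequence, or a truncated trailing record) are
#' skipped and counted rather than raising an error, so a single corrupt
#' record does not abort a run.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A data.frame with columns `id`, `seq`, `qual` (Phred+33 encoded),
#'   one row per well-formed record. Attributes `n_parsed` (records seen),
#'   `n_malformed`, and `malformed_records` (1-based record indices) report
#'   parsing outcomes.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n_rec <- length(lines) %/% 4L
  truncated <- length(lines) %% 4L != 0L
  if (n_rec == 0L) {
    out <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
    attr(out, "n_parsed") <- as.integer(truncated)
    attr(out, "n_malformed") <- as.integer(truncated)
    attr(out, "malformed_records") <- if (truncated) 1L else integer(0)
    return(out)
  }
  l1 <- lines[seq(1L, by = 4L, length.out = n_rec)]
  l2 <- lines[seq(2L, by = 4L, length.out = n_rec)]
  l3 <- lines[seq(3L, by = 4L, length.out = n_rec)]
  l4 <- lines[seq(4L, by = 4L, length.out = n_rec)]
  ok <- startsWith(l1, "@") & startsWith(l3, "+") &
    nzchar(l2) & nchar(l2) == nchar(l4)
  bad <- which(!ok)
  if (truncated) bad <- c(bad, n_rec + 1L)
  id <- sub("\\s.*$", "", sub("^@", "", l1[ok]))
  out <- data.frame(id = id, seq = toupper(l2[ok]), qual = l4[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_parsed") <- n_rec + as.integer(truncated)
  attr(out, "n_malformed") <- length(bad)
  attr(out, "malformed_records") <- as.integer(bad)
  out
}

#' Preprocessing configuration
#'
#' Describes the expected read layout: a molecular identifier (MID) of
#' `mid_length` nucleotides at `mid_offset`, followed by an exact
#' constant-region `anchor`, followed by the V(D)J-proximal payload. Reads are
#' trimmed to `payload_length` nucleotides starting at the anchor.
#'
#' @param anchor Constant-region nucleotide string that must occur exactly
#'   (with at most `max_mismatch` mismatches) for a read to be kept.
#' @param mid_length MID length in nucleotides (default 12).
#' @param payload_length Maximum payload length kept, counted from the start
#'   of the anchor (default 150).
#' @param mid_offset 1-based position of the first MID base in the read
#'   (default 1, i.e. the read starts with the MID).
#' @param min_payload Minimum acceptable payload length; shorter reads are
#'   rejected (default 100).
#' @param max_mismatch Number of mismatches tolerated in the anchor match
#'   (default 0, exact matching).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(anchor, mid_length = 12L, payload_length = 150L,
                              mid_offset = 1L, min_payload = 100L,
                              max_mismatch = 0L) {
  stopifnot(is.character(anchor), length(anchor) == 1L, nzchar(anchor),
            mid_length >= 1L, payload_length >= 1L, mid_offset >= 1L,
            min_payload >= 1L, max_mismatch >= 0L)
  structure(list(anchor = toupper(anchor), mid_length = as.integer(mid_length),
                 payload_length = as.integer(payload_length),
                 mid_offset = as.integer(mid_offset),
                 min_payload = as.integer(min_payload),
                 max_mismatch = as.integer(max_mismatch)),
            class = "preprocess_config")
}

#' Locate the constant-region anchor in reads
#'
#' Finds the first occurrence of the anchor at or after the end of the MID
#' (position `mid_offset + mid_length`). Matching is exact unless
#' `max_mismatch > 0`.
#'
#' @param seq Character vector of read sequences.
#' @param config A [preprocess_config()].
#' @return Integer vector of 1-based anchor start positions; `NA` where the
#'   anchor is absent.
#' @export
locate_anchor <- function(seq, config) {
  start <- config$mid_offset + config$mid_length  # first position after MID
  tail <- substring(seq, start)
  if (config$max_mismatch == 0L) {
    pos <- regexpr(config$anchor, tail, fixed = TRUE)
    out <- ifelse(pos > 0L, pos + start - 1L, NA_integer_)
    return(as.integer(out))
  }
  # mismatch-tolerant sliding comparison (rarely used; exact is the default)
  la <- nchar(config$anchor)
  anchor_chars <- strsplit(config$anchor, "")[[1]]
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n - start + 1L < la) return(NA_integer_)
    for (p in start:(n - la + 1L)) {
      window <- strsplit(substr(s, p, p + la - 1L), "")[[1]]
      if (sum(window != anchor_chars) <= config$max_mismatch)
        return(as.integer(p))
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Extract MIDs and anchored payloads from raw reads
#'
#' Applies the read-layout rules: reads without an (exact) anchor occurrence
#' after the MID are rejected (`no_anchor`); reads with `N` in the MID are
#' rejected (`ambiguous_mid`), since an ambiguous identifier cannot be
#' grouped; reads whose post-anchor payload is shorter than `min_payload` are
#' rejected (`short_payload`). Accepted reads are trimmed to `payload_length`
#' nucleotides starting at the anchor, with qualities sliced in step.
#'
#' @param reads A data.frame with columns `id`, `seq`, `qual` as returned by
#'   [read_fastq()].
#' @param config A [preprocess_config()].
#' @return A list with `reads` (data.frame `id`, `mid`, `payload`, `qual`,
#'   `mean_quality`) and `stats` (list: `parsed`, `accepted`, `rejected`
#'   named by reason).
#' @export
prepare_reads <- function(reads, config) {
  stopifnot(inherits(config, "preprocess_config"))
  n <- nrow(reads)
  if (n == 0L) {
    empty <- data.frame(id = character(0), mid = character(0),
                        payload = character(0), qual = character(0),
                        mean_quality = numeric(0), stringsAsFactors = FALSE)
    return(list(reads = empty,
                stats = list(parsed = 0L, accepted = 0L,
                             rejected = c(no_anchor = 0L, ambiguous_mid = 0L,
                                          short_payload = 0L))))
  }
  anchor_at <- locate_anchor(reads$seq, config)
  mid <- substr(reads$seq, config$mid_offset,
                config$mid_offset + config$mid_length - 1L)
  reason <- rep(NA_character_, n)
  reason[is.na(anchor_at)] <- "no_anchor"
  ambiguous <- is.na(reason) & grepl("[^ACGT]", mid)
  reason[ambiguous] <- "ambiguous_mid"
  end <- pmin(nchar(reads$seq), anchor_at + config$payload_length - 1L)
  plen <- end - anchor_at + 1L
  reason[is.na(reason) & plen < config$min_payload] <- "short_payload"
  keep <- is.na(reason)
  payload <- substr(reads$seq[keep], anchor_at[keep], end[keep])
  qual <- substr(reads$qual[keep], anchor_at[keep], end[keep])
  out <- data.frame(id = reads$id[keep], mid = mid[keep], payload = payload,
                    qual = qual, mean_quality = mean_phred(qual),
                    stringsAsFactors = FALSE)
  rej <- c(no_anchor = sum(reason == "no_anchor", na.rm = TRUE),
           ambiguous_mid = sum(reason == "ambiguous_mid", na.rm = TRUE),
           short_payload = sum(reason == "short_payload", na.rm = TRUE))
  list(reads = out,
       stats = list(parsed = n, accepted = sum(keep), rejected = rej))
}

#' Write / read a prepared-read manifest
#'
#' The manifest is a TSV with columns `id`, `mid`, `payload`, `qual`,
#' `mean_quality`, the on-disk interchange format between pipeline stages.
#'
#' @param prepared Prepared reads, the `reads` element of [prepare_reads()].
#' @param path Output file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the manifest data.frame.
#' @export
write_manifest <- function(prepared, path) {
  write_tsv(prepared, path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read_tsv(path, colClasses = c(id = "character", mid = "character",
                                payload = "character", qual = "character",
                                mean_quality = "numeric"))
}
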