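#' Count RNA molecules from prepared reads
#'
#' The full counting pipeline: group reads by MID, split each group into
#' edit-distance sub-clusters (one per inferred RNA molecule), build
#' quality-weighted consensus sequences, merge identical consensus into
#' clonotypes, then apply the clonotype filters (non-functional flagging,
#' one-edit neighbour collapse, MID read-count filter).
#'
#' With `subcluster = FALSE` each MID group yields a single consensus over all
#' of its reads (groups below `min_reads` reads are still dropped). This is
#' the comparison mode in which distinct molecules sharing an MID are merged
#' and chimeric consensus sequences arise; it exists to quantify the damage
#' sub-clustering prevents, not for production use.
#'
#' @param prepared Prepared-read data.frame (see [prepare_reads()]).
#' @param params A [cluster_params()].
#' @param frame_offset Reading-frame offset for non-functional flagging.
#' @param threshold_fraction MID read-count filter threshold (default 0.2).
#' @param subcluster Split MID groups into per-molecule sub-clusters
#'   (default `TRUE`).
#' @param collapse Apply one-edit neighbour collapse (default `TRUE`).
#' @param mid_filter Apply the MID read-count filter; `FALSE` yields
#'   uncorrected molecule counts (default `TRUE`).
#' @return A `clonotype_table` with an `"audit"` attribute recording read and
#'   clonotype conservation through the stages.
#' @export
count_repertoire <- function(prepared, params = cluster_params(),
                             frame_offset = 0L, threshold_fraction = 0.2,
                             subcluster = TRUE, collapse = TRUE,
                             mid_filter = TRUE) {
  if (subcluster) {
    sc <- subcluster_reads(prepared, params)
    records <- sc$subclusters
    n_assigned <- sum(!is.na(sc$assignment$subcluster_row))
  } else {
    records <- consensus_per_mid(prepared, params$min_reads)
    n_assigned <- sum(records$read_count)
  }
  ct <- merge_identical(records)
  ct <- filter_clonotypes(ct, frame_offset = frame_offset,
                          threshold_fraction = threshold_fraction,
                          collapse = collapse, mid_filter = mid_filter)
  audit <- attr(ct, "audit")
  audit <- c(list(reads_in = nrow(prepared), reads_assigned = n_assigned,
                  subclusters = nrow(records), subcluster = subcluster),
             audit)
  attr(ct, "audit") <- audit
  ct
}

# One consensus per MID group, regardless of internal distances (the
# no-sub-clustering comparison mode). Groups with fewer than min_reads reads
# are dropped.
consensus_per_mid <- function(prepared, min_reads = 2L) {
  if (nrow(prepared) == 0L)
    return(data.frame(mid = character(0), read_count = integer(0),
                      consensus = character(0), stringsAsFactors = FALSE))
  ord <- order(prepared$mid, prepared$id, method = "radix")
  p <- prepared[ord, , drop = FALSE]
  gcode <- cumsum(c(TRUE, p$mid[-1L] != p$mid[-nrow(p)]))
  sizes <- tabulate(gcode)
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  keep <- which(sizes >= min_reads)
  cons <- vapply(keep, function(g) {
    idx <- starts[g]:(starts[g] + sizes[g] - 1L)
    .consensus_cpp(p$payload[idx], p$qual[idx])
  }, character(1))
  data.frame(mid = p$mid[starts[keep]], read_count = sizes[keep],
             consensus = cons, stringsAsFactors = FALSE)
}

#' Run statistics as JSON
#'
#' Serializes a preprocessing/pipeline audit list to a JSON file.
#'
#' @param stats A named list (e.g. the `stats` element of [prepare_reads()]
#'   or the `"audit"` attribute of a `clonotype_table`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_stats <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
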