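#' Clustering parameters for MID sub-clustering
#'
#' @param distance_fraction Fraction of the seed read length used as the
#'   Levenshtein threshold when deciding whether a read descends from the same
#'   RNA molecule as the seed (default 0.15; rounded half-to-even, so 22 edits
#'   for a 150-nt payload).
#' @param min_reads Minimum reads per retained sub-cluster (default 2).
#'   Singletons cannot be distinguished from sequencing artifacts and are
#'   discarded.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(distance_fraction = 0.15, min_reads = 2L) {
  stopifnot(distance_fraction > 0, distance_fraction < 1, min_reads >= 2L)
  structure(list(distance_fraction = distance_fraction,
                 min_reads = as.integer(min_reads)),
            class = "cluster_params")
}

#' Levenshtein edit distance
#'
#' Standard unit-cost insertion/deletion/substitution edit distance, computed
#' by a banded dynamic program. Vectorized over pairs with recycling.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @param max_dist If non-negative, computation stops early and `max_dist + 1`
#'   is returned as soon as the distance is known to exceed `max_dist`.
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b, max_dist = -1L) {
  .lv_dist_cpp(as.character(a), as.character(b), as.integer(max_dist))
}

#' Group prepared reads by MID
#'
#' @param prepared Prepared-read data.frame (see [prepare_reads()]).
#' @return A named list of data.frames, one per distinct MID; every input read
#'   appears in exactly one group.
#' @export
group_by_mid <- function(prepared) {
  if (nrow(prepared) == 0L) return(structure(list(), names = character(0)))
  split(prepared, prepared$mid)
}

#' Sub-cluster one MID group into per-molecule read sets
#'
#' Greedy seeded quality-threshold clustering: the unassigned read with the
#' highest summed base quality (ties broken by smallest read id) seeds a
#' cluster of all unassigned reads within `round(distance_fraction * seed
#' length)` edits of it; the step repeats until no reads remain. Clusters with
#' fewer than `min_reads` members are discarded, as are two-read clusters
#' whose members are not identical strings (a lone disagreeing pair cannot be
#' error-corrected). Each retained sub-cluster is taken to represent one RNA
#' molecule.
#'
#' @param group A data.frame of prepared reads sharing one MID.
#' @param params A [cluster_params()].
#' @return A list with `clusters` (list of lists: `mid`, `members`
#'   data.frame, `consensus`, `read_count`) and `discarded` (data.frame of
#'   reads not assigned to any retained sub-cluster).
#' @export
qt_subcluster <- function(group, params = cluster_params()) {
  stopifnot(nrow(group) >= 1L, length(unique(group$mid)) == 1L)
  group <- group[order(group$id, method = "radix"), , drop = FALSE]
  res <- .cluster_groups_cpp(group$payload, group$qual,
                             rep(1L, nrow(group)),
                             params$distance_fraction, params$min_reads)
  clusters <- lapply(seq_along(res$read_count), function(k) {
    members <- group[res$assign == k, , drop = FALSE]
    list(mid = group$mid[1L], members = members,
         consensus = res$consensus[k], read_count = res$read_count[k])
  })
  list(clusters = clusters,
       discarded = group[res$assign == 0L, , drop = FALSE])
}

#' Sub-cluster all MID groups of a prepared-read set
#'
#' Vectorized driver for [qt_subcluster()] across every MID group; the
#' per-group algorithm is identical.
#'
#' @param prepared Prepared-read data.frame.
#' @param params A [cluster_params()].
#' @return A list with `subclusters` (data.frame `mid`, `subcluster_index`,
#'   `read_count`, `consensus`; one row per retained sub-cluster, i.e. per
#'   inferred RNA molecule) and `assignment` (data.frame `id`, `mid`,
#'   `subcluster_row` with `NA` for discarded reads, row index into
#'   `subclusters`).
#' @export
subcluster_reads <- function(prepared, params = cluster_params()) {
  if (nrow(prepared) == 0L) {
    return(list(subclusters = data.frame(mid = character(0),
                                         subcluster_index = integer(0),
                                         read_count = integer(0),
                                         consensus = character(0),
                                         stringsAsFactors = FALSE),
                assignment = data.frame(id = character(0), mid = character(0),
                                        subcluster_row = integer(0),
                                        stringsAsFactors = FALSE)))
  }
  ord <- order(prepared$mid, prepared$id, method = "radix")
  p <- prepared[ord, , drop = FALSE]
  gcode <- cumsum(c(TRUE, p$mid[-1L] != p$mid[-nrow(p)]))
  res <- .cluster_groups_cpp(p$payload, p$qual, as.integer(gcode),
                             params$distance_fraction, params$min_reads)
  mids_by_code <- p$mid[!duplicated(gcode)]
  sub <- data.frame(mid = mids_by_code[res$cluster_group],
                    subcluster_index = stats::ave(res$cluster_group,
                                                  res$cluster_group,
                                                  FUN = seq_along),
                    read_count = res$read_count, consensus = res$consensus,
                    stringsAsFactors = FALSE)
  assignment <- data.frame(id = p$id, mid = p$mid,
                           subcluster_row = ifelse(res$assign == 0L, NA_integer_,
                                                   res$assign),
                           stringsAsFactors = FALSE)
  list(subclusters = sub, assignment = assignment)
}

#' Quality-weighted consensus of a read set
#'
#' At each position of the modal read length, the base with the largest summed
#' Phred quality across members wins; ties break in the fixed order
#' A < C < G < T. Members whose length differs from the modal length do not
#' vote (no alignment is attempted), and `N` bases carry zero weight.
#'
#' @param seqs Character vector of member sequences, or a data.frame with
#'   `payload` and `qual` columns.
#' @param quals Phred+33 quality strings aligned to `seqs` (ignored when
#'   `seqs` is a data.frame).
#' @return The consensus nucleotide string.
#' @export
build_consensus <- function(seqs, quals = NULL) {
  if (is.data.frame(seqs)) {
    quals <- seqs$qual
    seqs <- seqs$payload
  }
  stopifnot(length(seqs) >= 1L, length(seqs) == length(quals))
  .consensus_cpp(as.character(seqs), as.character(quals))
}

#' Fraction of occupied MIDs containing multiple sub-clusters
#'
#' The observed counterpart of the Poisson occupancy prediction
#' [frac_needing_subclustering()]: among MID groups that yield at least one
#' retained sub-cluster, the fraction yielding two or more (i.e. MIDs that
#' tagged more than one RNA molecule).
#'
#' @param x Either the `subclusters` data.frame from [subcluster_reads()], or
#'   a prepared-read data.frame (in which case sub-clustering is run with
#'   `params`).
#' @param params A [cluster_params()], used only when `x` is a prepared-read
#'   data.frame.
#' @return A fraction in `[0, 1]`.
#' @export
fraction_mids_with_subclusters <- function(x, params = cluster_params()) {
  sub <- if (!is.null(x$subcluster_index)) x else subcluster_reads(x, params)$subclusters
  if (nrow(sub) == 0L)
    stop("no MID group yielded a retained sub-cluster; fraction undefined")
  per_mid <- table(sub$mid)
  sum(per_mid >= 2L) / length(per_mid)
}
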