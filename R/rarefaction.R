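#' Subsample reads uniformly without replacement
#'
#' @param reads A data.frame of reads (any row-per-read table).
#' @param fraction Fraction of reads to keep (`0 < fraction <= 1`); the
#'   subsample holds `round(fraction * n)` rows.
#' @param seed Optional seed for reproducibility.
#' @return The subsampled data.frame.
#' @export
subsample_reads <- function(reads, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(reads)
  k <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, k))
  reads[idx, , drop = FALSE]
}

# One shared permutation: taking the first round(f * n) rows for each f gives
# a nested chain of subsamples (each shallower sample is a subset of every
# deeper one).
nested_indices <- function(n, fractions, seed = NULL) {
  perm <- with_seed(seed, sample.int(n))
  lapply(fractions, function(f) perm[seq_len(round(f * n))])
}

#' Rarefaction curves over sequencing depth
#'
#' Runs the full counting pipeline on read subsamples of increasing depth and
#' records saturation statistics: `molecules` (surviving sub-clusters),
#' `unique_sequences` (clonotypes), and `single_copy_clones` (clonotypes with
#' exactly one RNA molecule, each backed by at least two identical reads).
#'
#' @param prepared Prepared-read data.frame.
#' @param fractions Ascending subsample fractions (default 0.1 to 1 by 0.1).
#' @param statistic Statistics to record (any subset of the three above).
#' @param seed Seed for the subsampling permutation.
#' @param nested Use nested subsamples — shallower samples are subsets of
#'   deeper ones (default `TRUE`); otherwise each fraction is drawn
#'   independently.
#' @param params,frame_offset,threshold_fraction,subcluster,collapse,mid_filter
#'   Passed to [count_repertoire()]; `mid_filter = FALSE` yields uncorrected
#'   curves.
#' @return A data.frame with columns `fraction`, `depth` (reads in the
#'   subsample), `statistic`, `value`.
#' @export
rarefaction_curve <- function(prepared, fractions = seq(0.1, 1, by = 0.1),
                              statistic = c("molecules", "unique_sequences",
                                            "single_copy_clones"),
                              seed = NULL, nested = TRUE,
                              params = cluster_params(), frame_offset = 0L,
                              threshold_fraction = 0.2, subcluster = TRUE,
                              collapse = TRUE, mid_filter = TRUE) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  stopifnot(!is.unsorted(fractions), all(fractions > 0), all(fractions <= 1))
  n <- nrow(prepared)
  idx <- if (nested) {
    nested_indices(n, fractions, seed)
  } else {
    lapply(seq_along(fractions), function(i) {
      with_seed(if (is.null(seed)) NULL else seed + i,
                sample.int(n, round(fractions[i] * n)))
    })
  }
  rows <- lapply(seq_along(fractions), function(i) {
    sub <- prepared[idx[[i]], , drop = FALSE]
    ct <- count_repertoire(sub, params = params, frame_offset = frame_offset,
                           threshold_fraction = threshold_fraction,
                           subcluster = subcluster, collapse = collapse,
                           mid_filter = mid_filter)
    vals <- c(molecules = sum(ct$molecule_count),
              unique_sequences = nrow(ct),
              single_copy_clones = sum(ct$molecule_count == 1L))
    data.frame(fraction = fractions[i], depth = nrow(sub),
               statistic = statistic, value = as.integer(vals[statistic]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap between clone sets at adjacent depths
#'
#' The fraction of clones in the deeper subsample that are also observed in
#' the shallower one: `|shallow intersect deep| / |deep|`.
#'
#' @param shallow,deep Character vectors of clone (consensus sequence)
#'   identities; `deep` comes from the deeper subsample.
#' @return A fraction in `[0, 1]`.
#' @export
overlap_percentage <- function(shallow, deep) {
  if (length(deep) == 0L)
    stop("overlap undefined: the deeper clone set is empty")
  length(intersect(shallow, deep)) / length(unique(deep))
}

#' Clone overlap across adjacent subsample depths
#'
#' Recomputes clonotypes at each subsample fraction (nested subsamples, so
#' the comparison of e.g. 0.9 against the full set is well defined) and
#' reports [overlap_percentage()] for each adjacent pair — 9 values for the
#' default 10-fraction grid. High overlap at the deep end indicates the
#' library was sequenced to saturation for the clone class considered.
#'
#' @inheritParams rarefaction_curve
#' @param clones Which clones to compare: `"single_copy"` (clonotypes with one
#'   RNA molecule, the most depth-sensitive class) or `"all"`.
#' @return A data.frame with columns `fraction_shallow`, `fraction_deep`,
#'   `overlap`.
#' @export
overlap_curve <- function(prepared, fractions = seq(0.1, 1, by = 0.1),
                          clones = c("single_copy", "all"), seed = NULL,
                          params = cluster_params(), frame_offset = 0L,
                          threshold_fraction = 0.2) {
  clones <- match.arg(clones)
  stopifnot(!is.unsorted(fractions), length(fractions) >= 2L)
  idx <- nested_indices(nrow(prepared), fractions, seed)
  sets <- lapply(idx, function(ii) {
    ct <- count_repertoire(prepared[ii, , drop = FALSE], params = params,
                           frame_offset = frame_offset,
                           threshold_fraction = threshold_fraction)
    if (clones == "single_copy") ct$seq[ct$molecule_count == 1L] else ct$seq
  })
  k <- length(fractions)
  data.frame(fraction_shallow = fractions[-k], fraction_deep = fractions[-1L],
             overlap = vapply(seq_len(k - 1L), function(i) {
               overlap_percentage(sets[[i]], sets[[i + 1L]])
             }, numeric(1)))
}

#' Clone-size distribution
#'
#' Exact frequency table of molecule counts across clonotypes.
#'
#' @param ct A `clonotype_table`.
#' @return A data.frame with columns `molecule_count` and `n_clonotypes`;
#'   `sum(n_clonotypes)` equals the number of clonotypes.
#' @export
clone_size_distribution <- function(ct) {
  tab <- table(ct$molecule_count)
  data.frame(molecule_count = as.integer(names(tab)),
             n_clonotypes = as.integer(tab))
}

#' Clonal-expansion summary
#'
#' Clonotypes with more than `threshold` RNA molecules are classed as
#' expanded; the summary reports how many there are and what fraction of all
#' RNA molecules they hold. The default threshold of 20 copies separates
#' antigen-expanded effector clones from the naive background.
#'
#' @param ct A `clonotype_table`.
#' @param threshold Molecule-count cutoff; a clone is expanded when its count
#'   strictly exceeds this (default 20).
#' @return An object of class `expansion_summary`: `threshold`,
#'   `expanded_clone_count`, `expanded_molecule_fraction`, `total_clones`,
#'   `total_molecules`.
#' @export
expansion_summary <- function(ct, threshold = 20L) {
  expanded <- ct$molecule_count > threshold
  total <- sum(ct$molecule_count)
  out <- list(threshold = threshold,
              expanded_clone_count = sum(expanded),
              expanded_molecule_fraction =
                if (total == 0L) 0 else sum(ct$molecule_count[expanded]) / total,
              total_clones = nrow(ct), total_molecules = total)
  class(out) <- "expansion_summary"
  out
}

#' @export
print.expansion_summary <- function(x, ...) {
  cat(sprintf("Expansion summary (> %d RNA copies): %d of %d clones expanded, %.2f%% of %d molecules\n",
              x$threshold, x$expanded_clone_count, x$total_clones,
              100 * x$expanded_molecule_fraction, x$total_molecules))
  invisible(x)
}
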