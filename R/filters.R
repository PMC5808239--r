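new_clonotype_table <- function(entries) {
  # entries: one row per retained sub-cluster (seq, mid, read_count)
  if (nrow(entries) == 0L) {
    ct <- data.frame(seq = character(0), molecule_count = integer(0),
                     total_reads = integer(0), n_mids = integer(0),
                     functional = logical(0), stringsAsFactors = FALSE)
  } else {
    f <- factor(entries$seq, levels = unique(entries$seq))
    ct <- data.frame(seq = levels(f),
                     molecule_count = as.integer(tabulate(f)),
                     total_reads = as.integer(
                       tapply(entries$read_count, f, sum)),
                     n_mids = as.integer(
                       tapply(entries$mid, f, function(m) length(unique(m)))),
                     functional = NA, stringsAsFactors = FALSE)
  }
  rownames(ct) <- NULL
  attr(ct, "entries") <- entries
  class(ct) <- c("clonotype_table", "data.frame")
  ct
}

#' Merge identical consensus sequences into clonotypes
#'
#' Sub-clusters with the same consensus sequence are aggregated into one
#' clonotype. Each sub-cluster remains a distinct countable entry (two
#' sub-clusters with the same sequence *and* the same MID still count as two
#' molecules), so `molecule_count` is the number of surviving sub-clusters
#' carrying the sequence.
#'
#' @param records A data.frame of consensus records with columns `seq` (or
#'   `consensus`), `mid`, `read_count` — typically the `subclusters` element
#'   of [subcluster_reads()].
#' @return A `clonotype_table`: a data.frame with columns `seq`,
#'   `molecule_count`, `total_reads`, `n_mids`, `functional`, carrying the
#'   per-sub-cluster entries as attribute `"entries"`.
#' @export
merge_identical <- function(records) {
  if (is.null(records$seq) && !is.null(records$consensus))
    names(records)[names(records) == "consensus"] <- "seq"
  stopifnot(all(c("seq", "mid", "read_count") %in% names(records)))
  new_clonotype_table(records[, c("seq", "mid", "read_count"), drop = FALSE])
}

#' Flag non-functional sequences
#'
#' A sequence is flagged non-functional when its translation in the reading
#' frame fixed by the constant-region anchor contains a stop codon. Full V/J
#' junction productivity calling is out of scope; the in-frame stop is the
#' operational criterion.
#'
#' @param x Character vector of nucleotide sequences, or a `clonotype_table`.
#' @param frame_offset 0, 1 or 2: offset of the first complete codon relative
#'   to the payload start.
#' @return For a character vector, a logical vector (`TRUE` = non-functional).
#'   For a `clonotype_table`, the table with its `functional` column filled
#'   in.
#' @export
flag_nonfunctional <- function(x, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  if (inherits(x, "clonotype_table")) {
    x$functional <- !flag_nonfunctional(x$seq, frame_offset)
    return(x)
  }
  vapply(x, function(s) {
    n <- nchar(s)
    starts <- seq.int(1L + frame_offset, by = 3L,
                      length.out = max(0L, (n - frame_offset) %/% 3L))
    if (length(starts) == 0L) return(FALSE)
    any(substring(s, starts, starts + 2L) %in% STOP_CODONS)
  }, logical(1), USE.NAMES = FALSE)
}

#' Collapse one-edit neighbour clonotypes
#'
#' Removes every clonotype whose sequence lies at Levenshtein distance exactly
#' 1 from another clonotype with a strictly greater molecule count. Such
#' satellites are PCR/sequencing-error derivatives of the larger clone.
#' Removal is decided against the pre-filter state in a single pass (no
#' chaining through already-removed sequences); ties in molecule count retain
#' both sequences.
#'
#' @param ct A `clonotype_table`.
#' @return The filtered `clonotype_table`; the number of removed clonotypes is
#'   recorded in attribute `"n_collapsed"`.
#' @export
collapse_neighbors <- function(ct) {
  stopifnot(inherits(ct, "clonotype_table"))
  if (nrow(ct) < 2L) {
    attr(ct, "n_collapsed") <- 0L
    return(ct)
  }
  pairs <- .neighbor_pairs_cpp(ct$seq)
  remove <- rep(FALSE, nrow(ct))
  if (nrow(pairs) > 0L) {
    ci <- ct$molecule_count[pairs[, 1L]]
    cj <- ct$molecule_count[pairs[, 2L]]
    remove[pairs[ci < cj, 1L]] <- TRUE
    remove[pairs[cj < ci, 2L]] <- TRUE
  }
  entries <- attr(ct, "entries")
  out <- new_clonotype_table(entries[entries$seq %in% ct$seq[!remove], ,
                                     drop = FALSE])
  out$functional <- ct$functional[!remove][match(out$seq, ct$seq[!remove])]
  attr(out, "n_collapsed") <- sum(remove)
  out
}

#' Remove low-read-count MID entries within each clonotype
#'
#' PCR errors in the MID create satellite identifiers whose read counts are
#' distinctly lower than those of true MIDs. Within each clonotype, MID
#' entries with fewer than `threshold_fraction` times the maximum read count
#' over that clonotype's MIDs are removed and the molecule count recomputed.
#' The default 20% threshold is the operational rule; [fit_nb_mixture()]
#' provides the two-component negative-binomial diagnostic that justifies it
#' and can supply a data-driven crossover count instead.
#'
#' @param ct A `clonotype_table`.
#' @param threshold_fraction Fraction of the per-clonotype maximum read count
#'   below which an MID entry is dropped (default 0.2).
#' @return The filtered `clonotype_table`; attribute `"n_mid_filtered"` counts
#'   removed MID entries.
#' @export
mid_readcount_filter <- function(ct, threshold_fraction = 0.2) {
  stopifnot(inherits(ct, "clonotype_table"), threshold_fraction >= 0,
            threshold_fraction <= 1)
  entries <- attr(ct, "entries")
  if (nrow(entries) == 0L) {
    attr(ct, "n_mid_filtered") <- 0L
    return(ct)
  }
  maxr <- stats::ave(entries$read_count, entries$seq, FUN = max)
  keep <- entries$read_count >= threshold_fraction * maxr
  out <- new_clonotype_table(entries[keep, , drop = FALSE])
  out$functional <- ct$functional[match(out$seq, ct$seq)]
  attr(out, "n_mid_filtered") <- sum(!keep)
  out
}

#' Fit a two-component negative-binomial mixture to MID read counts
#'
#' Models per-sub-cluster read counts as a mixture of a low-count component
#' (erroneous MIDs created by PCR errors) and a high-count component (true
#' MIDs), fitted by expectation-maximization. Initialization is
#' deterministic: component means start at the 10th and 90th percentiles of
#' the counts. The `crossover_count` — the smallest count at which the high
#' component's posterior exceeds the low component's — is the data-driven
#' analogue of the fixed 20%-of-maximum rule in [mid_readcount_filter()].
#'
#' @param read_counts Positive integer vector of per-sub-cluster read counts
#'   (at least 20 values with at least 2 distinct values for a meaningful
#'   fit).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `nb_mixture_fit`: `weight_low`, `mu`, `size`
#'   (low/high component parameters), `crossover_count`, `loglik`,
#'   `iterations`, and flags `degenerate` (all counts equal), `boundary`
#'   (mixture weight collapsed to 0 or 1), and `single_component` (boundary
#'   weight, or a likelihood-ratio comparison finds no support for a second
#'   component).
#' @export
fit_nb_mixture <- function(read_counts, max_iter = 500L, tol = 1e-8) {
  x <- as.integer(read_counts)
  stopifnot(length(x) >= 1L, all(x >= 1L))
  if (length(unique(x)) < 2L) {
    out <- list(weight_low = NA_real_, mu = c(low = unique(x), high = NA_real_),
                size = c(low = NA_real_, high = NA_real_),
                crossover_count = NA_integer_, loglik = NA_real_,
                iterations = 0L, degenerate = TRUE, boundary = FALSE,
                single_component = TRUE, n = length(x))
    class(out) <- "nb_mixture_fit"
    return(out)
  }
  if (length(x) < 20L)
    warning("fewer than 20 read counts; mixture fit may be unstable")
  wmle_nb <- function(x, w) {
    mu <- sum(w * x) / sum(w)
    f <- function(ls) -sum(w * dnbinom(x, mu = mu, size = exp(ls), log = TRUE))
    ls <- optimize(f, c(-7, 10))$minimum
    c(mu = mu, size = exp(ls))
  }
  mu <- unname(quantile(x, c(0.1, 0.9), type = 1))
  if (mu[1] == mu[2]) mu <- range(x)
  size <- c(1, 1)
  w1 <- 0.5
  ll_old <- -Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w1 * dnbinom(x, mu = mu[1], size = size[1])
    d2 <- (1 - w1) * dnbinom(x, mu = mu[2], size = size[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    w1 <- mean(r1)
    w1 <- min(max(w1, 1e-8), 1 - 1e-8)
    p1 <- wmle_nb(x, r1)
    p2 <- wmle_nb(x, 1 - r1)
    mu <- c(p1["mu"], p2["mu"])
    size <- c(p1["size"], p2["size"])
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu)
    size <- rev(size)
    w1 <- 1 - w1
  }
  boundary <- w1 < 1e-3 || w1 > 1 - 1e-3
  # single-component adequacy: likelihood-ratio comparison against one NB
  p0 <- wmle_nb(x, rep(1, length(x)))
  ll_single <- sum(dnbinom(x, mu = p0["mu"], size = p0["size"], log = TRUE))
  single_component <- boundary ||
    2 * (ll_old - ll_single) < stats::qchisq(0.99, df = 3)
  grid <- 0:max(x)
  post_hi <- (1 - w1) * dnbinom(grid, mu = mu[2], size = size[2]) >=
    w1 * dnbinom(grid, mu = mu[1], size = size[1])
  crossover <- if (any(post_hi)) grid[which(post_hi)[1]] else NA_integer_
  out <- list(weight_low = w1, mu = c(low = unname(mu[1]), high = unname(mu[2])),
              size = c(low = unname(size[1]), high = unname(size[2])),
              crossover_count = as.integer(crossover), loglik = ll_old,
              iterations = iter, degenerate = FALSE, boundary = boundary,
              single_component = single_component, n = length(x))
  class(out) <- "nb_mixture_fit"
  out
}

#' @export
print.nb_mixture_fit <- function(x, ...) {
  cat("Two-component negative-binomial mixture (", x$n, " counts)\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: all counts equal", x$mu[["low"]], "\n")
    return(invisible(x))
  }
  cat(sprintf("  low : weight %.3f, mean %.2f, size %.2f\n",
              x$weight_low, x$mu[["low"]], x$size[["low"]]))
  cat(sprintf("  high: weight %.3f, mean %.2f, size %.2f\n",
              1 - x$weight_low, x$mu[["high"]], x$size[["high"]]))
  cat("  crossover count:", x$crossover_count, "\n")
  if (x$single_component)
    cat("  note: a single component is adequate for these counts\n")
  invisible(x)
}

#' @export
print.clonotype_table <- function(x, n = 6L, ...) {
  cat("Clonotype table:", nrow(x), "clonotypes,",
      sum(x$molecule_count), "molecules,", sum(x$total_reads), "reads\n")
  if (nrow(x) > 0L) {
    show <- utils::head(x[order(-x$molecule_count), , drop = FALSE], n)
    show$seq <- paste0(substr(show$seq, 1L, 24L),
                       ifelse(nchar(show$seq) > 24L, "...", ""))
    print.data.frame(show, row.names = FALSE)
    if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
  }
  invisible(x)
}

#' Apply the post-clustering clonotype filters
#'
#' Runs the filter chain in order: non-functional flagging, one-edit neighbour
#' collapse, then the per-clonotype MID read-count filter. An audit of
#' removals is attached as attribute `"audit"`.
#'
#' @param ct A `clonotype_table` from [merge_identical()].
#' @param frame_offset Reading-frame offset for [flag_nonfunctional()].
#' @param threshold_fraction Threshold for [mid_readcount_filter()].
#' @param collapse,mid_filter Logical switches for the respective filters
#'   (both `TRUE` for the standard corrected pipeline; `mid_filter = FALSE`
#'   gives the uncorrected molecule counts).
#' @return The filtered `clonotype_table`.
#' @export
filter_clonotypes <- function(ct, frame_offset = 0L, threshold_fraction = 0.2,
                              collapse = TRUE, mid_filter = TRUE) {
  audit <- list(input_clonotypes = nrow(ct),
                input_molecules = sum(ct$molecule_count))
  ct <- flag_nonfunctional(ct, frame_offset)
  audit$nonfunctional_flagged <- sum(!ct$functional)
  if (collapse) {
    ct <- collapse_neighbors(ct)
    audit$neighbor_collapsed <- attr(ct, "n_collapsed")
  }
  if (mid_filter) {
    ct <- mid_readcount_filter(ct, threshold_fraction)
    audit$mid_entries_filtered <- attr(ct, "n_mid_filtered")
  }
  audit$output_clonotypes <- nrow(ct)
  audit$output_molecules <- sum(ct$molecule_count)
  attr(ct, "audit") <- audit
  ct
}
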