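#' Poisson model of MID tagging
#'
#' When `N` target RNA molecules each draw one of `M` equally likely molecular
#' identifiers independently, the number of molecules tagged by a given MID is
#' Poisson with rate `N/M`.
#'
#' @param N Number of tagged target molecules (non-negative).
#' @param M Total number of distinct MIDs; defaults to `4^mid_length`.
#' @param mid_length MID length used to derive `M` when `M` is missing.
#' @return An object of class `tagging_model` with elements `N` and `M`.
#' @export
tagging_model <- function(N, M = NULL, mid_length = 12L) {
  if (is.null(M)) M <- mid_space_size(mid_length)
  stopifnot(M >= 1, N >= 0)
  structure(list(N = as.numeric(N), M = as.numeric(M)),
            class = "tagging_model")
}

#' @export
print.tagging_model <- function(x, ...) {
  cat(sprintf("MID tagging model: N = %g molecules over M = %g identifiers (N/M = %.4g)\n",
              x$N, x$M, x$N / x$M))
  invisible(x)
}

#' Probability that one MID tags exactly k molecules
#'
#' `P_k = (N/M)^k / k! * exp(-N/M)`, the Poisson occupancy probability of the
#' tagging model.
#'
#' @param model A [tagging_model()].
#' @param k Non-negative integer vector of occupancy counts.
#' @return Probability vector, summing to 1 over all `k`.
#' @export
poisson_occupancy <- function(model, k) {
  stopifnot(inherits(model, "tagging_model"), all(k >= 0))
  dpois(k, lambda = model$N / model$M)
}

#' Fraction of occupied MIDs that need sub-clustering
#'
#' Among MIDs that tag at least one molecule, the fraction tagging two or
#' more: `F(k>1) = [1 - e^{-N/M} - (N/M) e^{-N/M}] / (1 - e^{-N/M})`. For a
#' 12-nt MID this is approximately linear in `N` for `N` below five million.
#'
#' @param model A [tagging_model()] with `N >= 1`.
#' @return A fraction in `[0, 1)`.
#' @export
frac_needing_subclustering <- function(model) {
  stopifnot(inherits(model, "tagging_model"))
  if (model$N <= 0)
    stop("F(k>1) is undefined when no molecules are tagged (N = 0)")
  r <- model$N / model$M
  occupied <- -expm1(-r)              # 1 - e^-r, stable for small r
  1 - r * exp(-r) / occupied
}

#' Size of the MID sequence space
#'
#' @param mid_length MID length in nucleotides.
#' @param alphabet_size Alphabet size (default 4).
#' @return `alphabet_size ^ mid_length` as an exact count (integer when it
#'   fits, double otherwise).
#' @export
mid_space_size <- function(mid_length, alphabet_size = 4L) {
  stopifnot(mid_length >= 1L, alphabet_size >= 2L)
  m <- as.numeric(alphabet_size)^as.numeric(mid_length)
  if (m <= .Machine$integer.max) as.integer(m) else m
}

#' Expected undercount from identical molecules sharing an MID
#'
#' When `n_identical` copies of the same RNA sequence each draw an MID
#' uniformly from `M` possibilities, copies that collide on the same MID are
#' merged by design and the molecule count is understated. The expected number
#' of distinct MIDs drawn is `M (1 - (1 - 1/M)^n)`, so the expected fractional
#' undercount is `(n - E[distinct]) / n`. The companion per-molecule
#' probability that a given copy shares its MID with at least one other copy,
#' `1 - (1 - 1/M)^(n-1)`, is also returned.
#'
#' @param M Number of distinct MIDs.
#' @param n_identical Number of identical molecules tagged (>= 1).
#' @return A list with `undercount`, `shared_mid_prob`, and
#'   `expected_distinct`.
#' @export
collision_undercount <- function(M, n_identical) {
  stopifnot(M >= 1, n_identical >= 1)
  n <- as.numeric(n_identical)
  M <- as.numeric(M)
  log1m <- log1p(-1 / M)
  expected_distinct <- M * -expm1(n * log1m)
  list(undercount = (n - expected_distinct) / n,
       shared_mid_prob = -expm1((n - 1) * log1m),
       expected_distinct = expected_distinct)
}

#' Sample clone sizes from a discrete power law
#'
#' Cell counts per clone are modelled as i.i.d. draws from the discrete power
#' law `f(x) \propto x^{-alpha}` on `xmin, ..., xmax` (density form
#' `(alpha - 1) x^{-alpha}` in the continuous limit). Sampling is by inverse
#' CDF on the exact normalized probability mass function.
#'
#' @param K Number of clones to draw.
#' @param alpha Power-law exponent (> 1).
#' @param xmin Lower cutoff (default 1).
#' @param xmax Upper truncation of the support (default `1e6`).
#' @param seed Optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return Integer vector of `K` clone sizes.
#' @export
sample_clone_sizes <- function(K, alpha, xmin = 1L, xmax = 1e6, seed = NULL) {
  stopifnot(K >= 1, alpha > 1, xmin >= 1, xmax >= xmin)
  support <- seq.int(xmin, xmax)
  logp <- -alpha * log(support)
  p <- exp(logp - max(logp))
  cdf <- cumsum(p) / sum(p)
  cdf[length(cdf)] <- 1
  with_seed(seed, {
    u <- runif(K)
    as.integer(support[findInterval(u, cdf, left.open = TRUE) + 1L])
  })
}

#' Fit a power-law exponent to clone sizes
#'
#' The default method is maximum likelihood combined with a
#' Kolmogorov–Smirnov goodness-of-fit scan over the lower cutoff `xmin`
#' (Clauset–Shalizi–Newman), delegated to [igraph::fit_power_law()] — the same
#' procedure used for clone-size distributions in the repertoire literature.
#' Alternatively, `method = "loglog"` fits a least-squares line to the
#' log–log size–frequency histogram and reports the negated slope, the
#' regression variant sometimes used to average an exponent across libraries.
#'
#' @param sizes Vector of positive clone sizes (at least 50 observations for
#'   the MLE/KS scan).
#' @param xmin Optional fixed lower cutoff; when `NULL` the cutoff is chosen
#'   by minimizing the KS distance.
#' @param method `"mle"` (default) or `"loglog"`.
#' @return An object of class `power_law_fit`: `alpha`, `xmin`, `ks_stat`
#'   (`NA` for the log–log method), `method`, and `n_tail` (observations at or
#'   above `xmin`).
#' @export
fit_power_law_alpha <- function(sizes, xmin = NULL,
                                method = c("mle", "loglog")) {
  method <- match.arg(method)
  sizes <- sizes[is.finite(sizes) & sizes > 0]
  if (length(unique(sizes)) < 2L)
    stop("cannot fit a power law: fewer than 2 distinct size values")
  if (method == "mle") {
    if (length(sizes) < 50L)
      stop("at least 50 observations are required for the MLE/KS fit")
    fit <- if (is.null(xmin)) {
      igraph::fit_power_law(sizes, implementation = "plfit")
    } else {
      igraph::fit_power_law(sizes, xmin = xmin, implementation = "plfit")
    }
    n_tail <- sum(sizes >= fit$xmin)
    if (n_tail < 10L)
      stop("fewer than 10 observations above the selected xmin")
    out <- list(alpha = fit$alpha, xmin = fit$xmin, ks_stat = fit$KS.stat,
                method = "mle", n_tail = n_tail)
  } else {
    tab <- table(sizes)
    v <- as.numeric(names(tab))
    f <- as.numeric(tab) / length(sizes)
    if (is.null(xmin)) xmin <- min(v)
    keep <- v >= xmin
    if (sum(keep) < 2L) stop("too few distinct sizes above xmin for a slope")
    # weighting by bin count tempers the noisy singleton tail of the histogram
    sl <- coef(lm(log(f[keep]) ~ log(v[keep]),
                  weights = as.numeric(tab)[keep]))[[2]]
    out <- list(alpha = -sl, xmin = xmin, ks_stat = NA_real_,
                method = "loglog", n_tail = sum(sizes >= xmin))
  }
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): alpha = %.3f, xmin = %g, n_tail = %d",
              x$method, x$alpha, x$xmin, x$n_tail))
  if (is.finite(x$ks_stat)) cat(sprintf(", KS = %.4f", x$ks_stat))
  cat("\n")
  invisible(x)
}

#' Expected detected clone diversity under subsampling
#'
#' With `K` clones of `x_i` cells each carrying `m` transcripts, the library
#' holds `N = m * sum(x)` molecules. Sampling `n` molecules without
#' replacement detects a clone unless all of its `m * x_i` molecules are
#' missed, so the expected number of detected clones is
#' `E(D) = K - sum_i C(N - m x_i, n) / C(N, n)`, evaluated via log-gamma to
#' stay finite for large `N`.
#'
#' @param m Transcript copies per cell (positive integer).
#' @param x Integer vector of clone cell counts.
#' @param n Number of molecules sampled (`0 <= n <= N`).
#' @return Expected number of detected clones.
#' @export
expected_diversity <- function(m, x, n) {
  stopifnot(m >= 1, all(x >= 1), n >= 0)
  N <- m * sum(x)
  if (n > N) stop("cannot sample more molecules than the library holds")
  avail <- N - m * x
  ratio <- ifelse(n > avail, 0, exp(lchoose(avail, n) - lchoose(N, n)))
  length(x) - sum(ratio)
}

#' Fraction of clone diversity covered by a subsample
#'
#' `P(D) = E(D) / K`, the expected fraction of clones detected when `n`
#' molecules are sampled; monotone non-decreasing in `n`.
#'
#' @inheritParams expected_diversity
#' @return A fraction in `[0, 1]`.
#' @export
diversity_coverage <- function(m, x, n) {
  expected_diversity(m, x, n) / length(x)
}

#' Estimate the integer per-cell transcript copy number
#'
#' Scans integer candidates `m` and selects the one whose model-predicted
#' diversity-coverage curve best matches the observed coverages in least
#' squares: `min_m sum_i (P(D_i | m, x) - D_obs_i)^2`. Both model and observed
#' coverages are scaled so that the curve equals 1 at `reference_fraction`.
#' The clone-size vector is drawn from the fitted power law with a fixed seed
#' shared across candidates, so residual differences reflect `m` only.
#'
#' @param coverages A data.frame with columns `fraction` (RNA input fraction)
#'   and `coverage` (observed diversity coverage, scaled to 1 at the reference
#'   fraction; if a row at `reference_fraction` is present the column is
#'   rescaled by it).
#' @param alpha Power-law exponent of the clone-size distribution (from
#'   [fit_power_law_alpha()]).
#' @param K Number of clones used for the model curves.
#' @param reference_fraction Input fraction whose coverage defines the scale
#'   (default 0.9).
#' @param m_range Integer candidates for the copy number (default `1:30`).
#' @param xmax Truncation of the sampled clone-size distribution.
#' @param seed Seed for the clone-size draw (shared across candidates).
#' @return An object of class `copy_number_fit`: `m_hat`, `residuals`
#'   (data.frame `m`, `rss`), `tied` (TRUE when the minimizer was not unique;
#'   the smallest `m` is returned), plus the call parameters.
#' @export
estimate_copy_number <- function(coverages, alpha, K,
                                 reference_fraction = 0.9, m_range = 1:30,
                                 xmax = 1e6, seed = NULL) {
  stopifnot(is.data.frame(coverages),
            all(c("fraction", "coverage") %in% names(coverages)))
  if (nrow(coverages) < 2L)
    stop("at least 2 coverage points are required to fit the copy number")
  stopifnot(all(coverages$fraction > 0), all(coverages$fraction <= 1),
            alpha > 1, K >= 1, all(m_range >= 1))
  ref_row <- which(abs(coverages$fraction - reference_fraction) < 1e-9)
  obs <- coverages$coverage
  if (length(ref_row) == 1L && abs(obs[ref_row] - 1) > 1e-12)
    obs <- obs / obs[ref_row]
  x <- sample_clone_sizes(K, alpha, xmax = xmax, seed = seed)
  rss <- vapply(m_range, function(m) {
    N <- m * sum(x)
    pred <- vapply(coverages$fraction,
                   function(f) diversity_coverage(m, x, round(f * N)),
                   numeric(1))
    ref <- diversity_coverage(m, x, round(reference_fraction * N))
    sum((pred / ref - obs)^2)
  }, numeric(1))
  best <- which(rss == min(rss))
  out <- list(m_hat = as.integer(m_range[best[1L]]),
              residuals = data.frame(m = as.integer(m_range), rss = rss),
              tied = length(best) > 1L, alpha = alpha, K = as.integer(K),
              reference_fraction = reference_fraction)
  class(out) <- "copy_number_fit"
  out
}

#' @export
print.copy_number_fit <- function(x, ...) {
  cat(sprintf("Copy-number fit: m = %d (alpha = %.3f, K = %d, reference fraction %.2f)\n",
              x$m_hat, x$alpha, x$K, x$reference_fraction))
  if (x$tied) cat("  note: minimizer not unique; smallest m reported\n")
  r <- x$residuals
  show <- r[order(r$rss), , drop = FALSE][seq_len(min(5L, nrow(r))), ]
  cat("  best candidates (m: rss):",
      paste(sprintf("%d: %.3g", show$m, show$rss), collapse = ", "), "\n")
  invisible(x)
}

#' Fold expansion of a clone relative to its precursor frequency
#'
#' `(clone_cells / population_cells) / precursor_frequency`: how many times a
#' clone's share of the population exceeds the naive precursor frequency of
#' cells with that specificity.
#'
#' @param clone_cells Cells in the clone (positive, at most
#'   `population_cells`).
#' @param population_cells Cells in the population containing the clone.
#' @param precursor_frequency Precursor frequency of the specificity
#'   (fraction, e.g. `1e-5` for 1 in 100,000).
#' @return The fold expansion (numeric).
#' @export
fold_expansion <- function(clone_cells, population_cells,
                           precursor_frequency) {
  if (any(c(clone_cells, population_cells, precursor_frequency) <= 0))
    stop("all inputs must be positive")
  if (clone_cells > population_cells)
    stop("clone_cells cannot exceed population_cells")
  (clone_cells / population_cells) / precursor_frequency
}
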