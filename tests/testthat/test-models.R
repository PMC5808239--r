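test_that("Poisson MID occupancy is a proper distribution", {
  m0 <- tagging_model(N = 0, mid_length = 12L)
  expect_equal(poisson_occupancy(m0, 0L), 1)
  expect_equal(poisson_occupancy(m0, 1:5), rep(0, 5))
  m1 <- tagging_model(N = mid_space_size(12), mid_length = 12L)  # N/M = 1
  expect_equal(poisson_occupancy(m1, 1L), exp(-1), tolerance = 1e-12)
  expect_equal(sum(poisson_occupancy(m1, 0:50)), 1, tolerance = 1e-12)
})

test_that("the multi-tagging fraction matches a multinomial simulation and is monotone", {
  expect_error(frac_needing_subclustering(tagging_model(N = 0)), "undefined")
  # small-ratio limit: F ~ (N/M)/2
  f_small <- frac_needing_subclustering(tagging_model(N = 10, M = 1e7))
  expect_equal(f_small, 10 / 1e7 / 2, tolerance = 1e-3)
  # Monte-Carlo oracle: N molecules into M MIDs, count multi-occupied MIDs
  M <- 1000L; N <- 300L; reps <- 20000L
  pred <- frac_needing_subclustering(tagging_model(N = N, M = M))
  sim <- withr::with_seed(41, vapply(seq_len(reps), function(i) {
    occ <- tabulate(sample.int(M, N, replace = TRUE), M)
    sum(occ > 1) / sum(occ > 0)
  }, numeric(1)))
  se <- sd(sim) / sqrt(reps)
  expect_lt(abs(mean(sim) - pred), 3 * se)
  # monotone increasing in N at fixed M
  fs <- vapply(c(1e4, 1e5, 1e6, 5e6), function(n)
    frac_needing_subclustering(tagging_model(N = n)), numeric(1))
  expect_true(all(diff(fs) > 0))
  expect_true(all(fs >= 0 & fs < 1))
})

test_that("MID space size is exact", {
  expect_identical(mid_space_size(1L), 4L)
  expect_identical(mid_space_size(2L), 16L)
  expect_identical(mid_space_size(12L), 16777216L)
})

test_that("collision undercount matches a birthday-problem simulation and its limits", {
  expect_equal(collision_undercount(100, 1)$undercount, 0)
  # Monte-Carlo oracle at M = 100, n = 50
  M <- 100L; n <- 50L; reps <- 20000L
  cu <- collision_undercount(M, n)
  sim <- withr::with_seed(43, vapply(seq_len(reps), function(i) {
    (n - length(unique(sample.int(M, n, replace = TRUE)))) / n
  }, numeric(1)))
  se <- sd(sim) / sqrt(reps)
  expect_lt(abs(mean(sim) - cu$undercount), 3 * se)
  # increases with n at fixed M; vanishes as M grows at fixed n
  u_n <- vapply(c(10, 100, 1000), function(k)
    collision_undercount(1e4, k)$undercount, numeric(1))
  expect_true(all(diff(u_n) > 0))
  u_M <- vapply(c(1e4, 1e6, 1e8), function(m)
    collision_undercount(m, 1000)$undercount, numeric(1))
  expect_true(all(diff(u_M) < 0))
  expect_lt(u_M[3], 1e-5)
})

test_that("clone-size sampling follows the discrete power law reproducibly", {
  # very large alpha concentrates all mass at xmin
  expect_true(all(sample_clone_sizes(500, alpha = 50, seed = 1) == 1L))
  expect_identical(sample_clone_sizes(100, 2.5, seed = 9),
                   sample_clone_sizes(100, 2.5, seed = 9))
  # binned goodness of fit against the exact pmf
  K <- 1e5; alpha <- 2.5
  x <- sample_clone_sizes(K, alpha, seed = 7)
  support <- 1:30
  p <- support^-alpha
  p <- p / (sum(p) + sum(seq(31, 1e6)^-alpha))
  obs <- c(tabulate(x[x <= 30], 30), sum(x > 30))
  gof <- suppressWarnings(stats::chisq.test(obs, p = c(p, 1 - sum(p))))
  expect_gt(gof$p.value, 0.01)
})

test_that("power-law exponent fitting recovers the truth and fails loudly otherwise", {
  x <- sample_clone_sizes(1e5, 2.5, seed = 11)
  fit <- fit_power_law_alpha(x)
  expect_gt(fit$alpha, 2.4)
  expect_lt(fit$alpha, 2.6)
  expect_error(fit_power_law_alpha(rep(3, 100)), "distinct")
  expect_error(fit_power_law_alpha(sample_clone_sizes(40, 2.5, seed = 1)),
               "50 observations")
  # log-log regression variant gives a slope in the right region
  fit2 <- fit_power_law_alpha(x, method = "loglog")
  expect_equal(fit2$method, "loglog")
  expect_lt(abs(fit2$alpha - 2.5), 0.5)
})

test_that("expected diversity obeys its boundary cases and a sampling oracle", {
  x <- rep(1L, 50); m <- 3L; N <- m * sum(x)
  expect_equal(expected_diversity(m, x, N), 50)
  expect_equal(expected_diversity(m, x, 0L), 0)
  expect_error(expected_diversity(m, x, N + 1L), "more molecules")
  # without-replacement sampling oracle at modest size
  labels <- rep(seq_along(x), each = m)
  for (n in c(25L, 125L)) {
    E <- expected_diversity(m, x, n)
    sim <- withr::with_seed(47, vapply(seq_len(20000L), function(i)
      length(unique(labels[sample.int(N, n)])), numeric(1)))
    expect_lt(abs(E - mean(sim)), 3 * sd(sim) / sqrt(length(sim)))
  }
  # heterogeneous clone sizes, larger clones detected more readily
  x2 <- c(10L, rep(1L, 20))
  E2 <- expected_diversity(2L, x2, 10L)
  expect_true(E2 > 0 && E2 < 21)
})

test_that("diversity coverage is monotone with correct limits", {
  x <- sample_clone_sizes(500, 2.5, seed = 3)
  m <- 3L; N <- m * sum(x)
  expect_equal(diversity_coverage(m, x, N), 1)
  grid <- round(seq(0, N, length.out = 20))
  cov <- vapply(grid, function(n) diversity_coverage(m, x, n), numeric(1))
  expect_true(all(diff(cov) >= 0))
  # single-cell clones: P(D) ~ 1 - (1 - f)^m for N >> m
  x3 <- rep(1L, 2000); f <- 0.3; N3 <- m * length(x3)
  expect_equal(diversity_coverage(m, x3, round(f * N3)), 1 - (1 - f)^m,
               tolerance = 2e-3)
})

test_that("integer copy-number estimation recovers the generating value", {
  fractions <- c(0.1, 0.3, 0.4, 0.5, 0.9)
  K <- 2000L; alpha <- 2.5; m_true <- 3L
  x <- sample_clone_sizes(K, alpha, seed = 71)
  N <- m_true * sum(x)
  ref <- diversity_coverage(m_true, x, round(0.9 * N))
  obs <- vapply(fractions, function(f)
    diversity_coverage(m_true, x, round(f * N)), numeric(1)) / ref
  fit <- estimate_copy_number(data.frame(fraction = fractions, coverage = obs),
                              alpha = alpha, K = K, m_range = 1:10, seed = 72)
  expect_equal(fit$m_hat, m_true)
  # minimizer property
  expect_true(all(fit$residuals$rss >=
                    fit$residuals$rss[fit$residuals$m == fit$m_hat]))
  expect_error(estimate_copy_number(data.frame(fraction = 0.5, coverage = 0.8),
                                    alpha = 2.5, K = 100), "at least 2")
})

test_that("fold expansion follows clone share over precursor frequency", {
  expect_gte(fold_expansion(70000, 7700000, 1e-5), 900)
  expect_equal(fold_expansion(70000, 7700000, 1e-5), (7e4 / 7.7e6) / 1e-5)
  expect_equal(fold_expansion(10, 1e6, 1e-5), 1)
  expect_equal(fold_expansion(20, 1e6, 1e-5),
               2 * fold_expansion(10, 1e6, 1e-5))
  expect_error(fold_expansion(0, 100, 1e-5), "positive")
  expect_error(fold_expansion(200, 100, 1e-5), "exceed")
})
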