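test_that("identical consensus sequences merge into clonotypes with conserved counts", {
  rec <- data.frame(seq = c("AAAA", "AAAA", "CCCC"),
                    mid = c("m1", "m2", "m3"),
                    read_count = c(5L, 7L, 2L), stringsAsFactors = FALSE)
  ct <- merge_identical(rec)
  expect_s3_class(ct, "clonotype_table")
  expect_equal(ct$molecule_count[ct$seq == "AAAA"], 2L)
  expect_equal(ct$total_reads[ct$seq == "AAAA"], 12L)
  expect_equal(ct$molecule_count[ct$seq == "CCCC"], 1L)

  expect_equal(nrow(merge_identical(rec[0, ])), 0L)

  # same sequence under the same MID stays two countable entries
  rec2 <- data.frame(seq = "AAAA", mid = c("m1", "m1"),
                     read_count = c(4L, 3L), stringsAsFactors = FALSE)
  ct2 <- merge_identical(rec2)
  expect_equal(ct2$molecule_count, 2L)
  expect_equal(ct2$n_mids, 1L)

  # conservation on simulated data: one molecule per retained sub-cluster
  sim <- simulate_reads(small_sim_config(seed = 17))
  sub <- subcluster_reads(prepare_sim(sim)$reads)$subclusters
  expect_equal(sum(merge_identical(sub)$molecule_count), nrow(sub))
})

test_that("non-functional flagging finds in-frame stop codons", {
  expect_true(flag_nonfunctional("ATGTAAGGG", 0L))
  expect_false(flag_nonfunctional("ATGGCAGGA", 0L))
  # TAA out of frame is not a stop
  expect_false(flag_nonfunctional("ATAAGCGGC", 0L))
  expect_true(flag_nonfunctional("CTAAGCGGC", 1L))
  # simulated nonproductive clones carry an in-frame stop; all are flagged
  cfg <- small_sim_config(seed = 19, nonproductive_fraction = 0.4,
                          pcr_error_rate = 0, seq_error_rate = 0)
  sim <- simulate_reads(cfg)
  ct <- count_repertoire(prepare_sim(sim)$reads, frame_offset = 0L)
  truth <- sim$truth$clones
  flagged <- !ct$functional[match(truth$seq, ct$seq)]
  expect_identical(flagged, !truth$productive)
  expect_gt(sum(!truth$productive), 0L)
})

test_that("one-edit neighbour collapse removes satellites, keeps ties, never chains", {
  s <- strrep("ACGT", 10)
  s_sat <- paste0("T", substr(s, 2, 40))        # 1 substitution from s
  entries <- data.frame(seq = rep(c(s, s_sat), c(10, 1)),
                        mid = sprintf("m%02d", 1:11),
                        read_count = 5L, stringsAsFactors = FALSE)
  ct <- collapse_neighbors(merge_identical(entries))
  expect_equal(ct$seq, s)
  expect_equal(attr(ct, "n_collapsed"), 1L)

  # ties retain both
  tie <- data.frame(seq = rep(c(s, s_sat), c(3, 3)), mid = sprintf("m%d", 1:6),
                    read_count = 2L, stringsAsFactors = FALSE)
  ct2 <- collapse_neighbors(merge_identical(tie))
  expect_setequal(ct2$seq, c(s, s_sat))

  # no chaining: c is only removed because of b's pre-filter count
  s_b <- s_sat
  s_c <- paste0("TG", substr(s, 3, 40))         # 1 edit from b, 2 from s
  chain <- data.frame(seq = rep(c(s, s_b, s_c), c(5, 3, 1)),
                      mid = sprintf("m%02d", 1:9), read_count = 3L,
                      stringsAsFactors = FALSE)
  ct3 <- collapse_neighbors(merge_identical(chain))
  expect_equal(ct3$seq, s)
  # but when b survives by tie, c is still judged against pre-filter b
  chain2 <- data.frame(seq = rep(c(s, s_b, s_c), c(3, 3, 1)),
                       mid = sprintf("m%02d", 1:7), read_count = 3L,
                       stringsAsFactors = FALSE)
  ct4 <- collapse_neighbors(merge_identical(chain2))
  expect_setequal(ct4$seq, c(s, s_b))
})

test_that("MID read-count filter drops entries below 20% of the clonotype maximum", {
  s <- strrep("ACGT", 10)
  entries <- data.frame(seq = s, mid = c("m1", "m2", "m3"),
                        read_count = c(100L, 25L, 19L), stringsAsFactors = FALSE)
  ct <- mid_readcount_filter(merge_identical(entries))
  expect_equal(ct$molecule_count, 2L)
  expect_equal(attr(ct, "n_mid_filtered"), 1L)
  # exactly at the threshold is kept
  ent2 <- data.frame(seq = s, mid = c("m1", "m2"), read_count = c(100L, 20L),
                     stringsAsFactors = FALSE)
  expect_equal(mid_readcount_filter(merge_identical(ent2))$molecule_count, 2L)
  # a single-MID clonotype is its own maximum, hence unchanged
  ent3 <- data.frame(seq = s, mid = "m1", read_count = 2L,
                     stringsAsFactors = FALSE)
  expect_equal(mid_readcount_filter(merge_identical(ent3))$molecule_count, 1L)
})

test_that("filters are order-independent in their input and only remove", {
  sim <- simulate_reads(small_sim_config(seed = 23))
  sub <- subcluster_reads(prepare_sim(sim)$reads)$subclusters
  perm <- withr::with_seed(1, sample(nrow(sub)))
  a <- filter_clonotypes(merge_identical(sub))
  b <- filter_clonotypes(merge_identical(sub[perm, , drop = FALSE]))
  ka <- a[order(a$seq), c("seq", "molecule_count", "total_reads")]
  kb <- b[order(b$seq), c("seq", "molecule_count", "total_reads")]
  rownames(ka) <- rownames(kb) <- NULL
  expect_identical(as.data.frame(ka), as.data.frame(kb))
  # monotonicity: no filter creates sequences or increases counts
  raw <- merge_identical(sub)
  expect_true(all(a$seq %in% raw$seq))
  expect_true(all(a$molecule_count <=
                    raw$molecule_count[match(a$seq, raw$seq)]))
})

test_that("negative-binomial mixture EM recovers well-separated components", {
  set.seed(4)
  counts <- c(rnbinom(500, mu = 2, size = 1) + 1L,
              rnbinom(500, mu = 60, size = 5) + 1L)
  fit <- fit_nb_mixture(counts)
  # true post-shift means are 3 and 61
  expect_lt(abs(fit$mu[["low"]] - 3) / 3, 0.25)
  expect_lt(abs(fit$mu[["high"]] - 61) / 61, 0.25)
  expect_false(fit$single_component)
  expect_true(fit$crossover_count > 2 && fit$crossover_count < 40)

  # all counts equal -> degenerate flag
  d <- fit_nb_mixture(rep(7L, 30))
  expect_true(d$degenerate)

  # a single negative binomial offers no support for a second component
  s <- fit_nb_mixture(rnbinom(400, mu = 20, size = 3) + 1L)
  expect_true(s$single_component)
})
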