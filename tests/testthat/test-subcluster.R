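test_that("levenshtein matches a dynamic-programming reference", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("ACGT", "AGT"), 1L)
  expect_equal(levenshtein("", "ACGT"), 4L)
  set.seed(11)
  a <- midcount:::random_dna(150, 30)
  b <- midcount:::random_dna(150, 30)
  expect_identical(levenshtein(a, b), mapply(lv_ref, a, b, USE.NAMES = FALSE))
  # symmetry and identity
  expect_identical(levenshtein(a, b), levenshtein(b, a))
  expect_true(all(levenshtein(a, a) == 0L))
  # cutoff agrees with the full distance up to the cutoff
  d_full <- levenshtein(a, b)
  d_cut <- levenshtein(a, b, max_dist = 8L)
  expect_identical(d_cut <= 8L, d_full <= 8L)
  expect_identical(d_cut[d_full <= 8L], d_full[d_full <= 8L])
})

test_that("reads group by MID with conservation", {
  r <- make_reads(c("AAAA", "AAAT", "CCCC"), mids = c("GG", "GG", "TT"))
  g <- group_by_mid(r)
  expect_equal(sort(names(g)), c("GG", "TT"))
  expect_equal(vapply(g, nrow, integer(1))[["GG"]], 2L)
  expect_equal(nrow(group_by_mid(r[0, ])[["x"]]), NULL)
  expect_length(group_by_mid(r[0, ]), 0L)

  sim <- simulate_reads(small_sim_config(seed = 8))
  prep <- prepare_sim(sim)$reads
  g <- group_by_mid(prep)
  expect_equal(sum(vapply(g, nrow, integer(1))), nrow(prep))
})

test_that("quality-threshold sub-clustering separates molecules and applies the two-read rule", {
  p <- cluster_params()
  # five identical reads -> one sub-cluster of five
  g <- make_reads(rep(strrep("ACGT", 10), 5), mids = rep("AAAA", 5))
  res <- qt_subcluster(g, p)
  expect_length(res$clusters, 1L)
  expect_equal(res$clusters[[1]]$read_count, 5L)
  expect_equal(nrow(res$discarded), 0L)

  # two reads differing at one position -> both discarded
  g2 <- make_reads(c(strrep("ACGT", 10), paste0("T", substr(strrep("ACGT", 10), 2, 40))),
                   mids = rep("AAAA", 2))
  res2 <- qt_subcluster(g2, p)
  expect_length(res2$clusters, 0L)
  expect_equal(nrow(res2$discarded), 2L)

  # a group mixing two well-separated molecules splits along the truth
  set.seed(21)
  mol <- midcount:::random_dna(2, 150)
  while (levenshtein(mol[1], mol[2]) < 40) mol <- midcount:::random_dna(2, 150)
  g3 <- make_reads(rep(mol, c(4, 3)), mids = rep("AAAA", 7))
  res3 <- qt_subcluster(g3, p)
  expect_length(res3$clusters, 2L)
  expect_setequal(vapply(res3$clusters, function(cl) cl$consensus, character(1)), mol)
  expect_setequal(vapply(res3$clusters, function(cl) cl$read_count, integer(1)), c(4L, 3L))

  # partition property: members plus discarded reads exactly partition the group
  ids <- c(unlist(lapply(res3$clusters, function(cl) cl$members$id)),
           res3$discarded$id)
  expect_setequal(ids, g3$id)
  expect_equal(length(ids), nrow(g3))
})

test_that("sub-clustering all groups matches the simulator's molecule partition", {
  # 12-nt MIDs so no two molecules share an identifier at this scale
  sim <- simulate_reads(small_sim_config(seed = 13, seq_error_rate = 0,
                                         pcr_error_rate = 0,
                                         mid_length = 12L))
  prep <- prepare_sim(sim)$reads
  sc <- subcluster_reads(prep, cluster_params())
  # with zero errors every retained sub-cluster is one true molecule
  truth_mol <- sim$read_map$molecule_id[match(sc$assignment$id, sim$read_map$id)]
  assigned <- !is.na(sc$assignment$subcluster_row)
  tab <- table(sc$assignment$subcluster_row[assigned], truth_mol[assigned])
  expect_true(all(rowSums(tab > 0) == 1L))  # no sub-cluster mixes molecules
  # molecules with >= 2 reads are all recovered
  depth <- table(truth_mol)
  expect_equal(nrow(sc$subclusters), sum(depth >= 2L))
  # consensus equals the true molecule sequence
  cons_mol <- truth_mol[assigned][match(seq_len(nrow(sc$subclusters)),
                                        sc$assignment$subcluster_row[assigned])]
  truth_seq <- sim$truth$clones$seq[sim$truth$molecules$clone_id[cons_mol]]
  expect_identical(sc$subclusters$consensus, truth_seq)
})

test_that("consensus is quality-weighted with deterministic tie-breaks", {
  s <- strrep("GATC", 8)
  expect_equal(build_consensus(rep(s, 3), rep(qual_str(32), 3)), s)
  # position-2 weights C:60 vs G:40 -> C wins
  expect_equal(build_consensus(c("AC", "AC", "AG"),
                               c(qual_str(2, 30), qual_str(2, 30),
                                 paste0(qual_str(1, 30), qual_str(1, 40)))),
               "AC")
  # equal weights tie-break in base order A < C < G < T
  expect_equal(build_consensus(c("AA", "AC"), c(qual_str(2), qual_str(2))), "AA")
  expect_equal(build_consensus(c("AT", "AG"), c(qual_str(2), qual_str(2))), "AG")
  # N carries no weight
  expect_equal(build_consensus(c("AN", "AC"), c(qual_str(2, 40), qual_str(2, 2))),
               "AC")
  # members of non-modal length do not vote
  expect_equal(build_consensus(c("AAAA", "AAAA", "CC"),
                               c(qual_str(4), qual_str(4), qual_str(2, 40))),
               "AAAA")
  # idempotence: copies of one sequence give that sequence whatever the quals
  set.seed(3)
  for (i in 1:5) {
    s <- midcount:::random_dna(1, 20)
    q <- vapply(sample(2:40, 4, TRUE), function(x) qual_str(20, x), character(1))
    expect_equal(build_consensus(rep(s, 4), q), s)
  }
})

test_that("fraction of MIDs with sub-clusters counts multi-molecule identifiers", {
  p <- cluster_params()
  s1 <- strrep("ACGT", 10)
  # all groups single-molecule -> 0
  r <- make_reads(rep(s1, 4), mids = rep(c("AA", "CC"), each = 2))
  expect_equal(fraction_mids_with_subclusters(r, p), 0)
  # one group with two well-separated molecules, one single -> 1/2
  set.seed(31)
  mol <- midcount:::random_dna(2, 150)
  while (levenshtein(mol[1], mol[2]) < 40) mol <- midcount:::random_dna(2, 150)
  r2 <- make_reads(c(rep(mol, each = 2), s1, s1),
                   mids = c(rep("AA", 4), "CC", "CC"))
  expect_equal(fraction_mids_with_subclusters(r2, p), 0.5)
  # no retained sub-cluster at all -> undefined, signaled
  r3 <- make_reads(s1, mids = "AA")
  expect_error(fraction_mids_with_subclusters(r3, p), "undefined")
})

test_that("observed multi-molecule MID fraction matches the Poisson occupancy model", {
  # high-collision regime: 6-nt MIDs, ~800 molecules over 4096 identifiers
  cfg <- sim_config(K = 150L, alpha = 2.5, m = 3L, mid_length = 6L,
                    reads_per_molecule_mean = 30, seq_error_rate = 1e-3,
                    seed = 202)
  sim <- simulate_reads(cfg)
  prep <- prepare_sim(sim)$reads
  sub <- subcluster_reads(prep, cluster_params())$subclusters
  obs <- fraction_mids_with_subclusters(sub)
  pred <- frac_needing_subclustering(
    tagging_model(N = nrow(sim$truth$molecules), M = mid_space_size(6)))
  n_occ <- length(unique(sub$mid))
  se <- sqrt(pred * (1 - pred) / n_occ)
  expect_lt(abs(obs - pred), 3 * se)
})
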