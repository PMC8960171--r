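test_that("identical reads form a single cluster", {
  cl <- cluster_molecule_reads(rep("ACGTACGTAC", 5))
  expect_equal(cl, rep(1L, 5))
})

test_that("the 0.9 identity threshold is inclusive", {
  # two length-10 reads differing at one position: identity exactly 0.9
  a <- "ACGTACGTAC"
  b <- "ACGTACGTAA"
  expect_equal(cluster_molecule_reads(c(a, b)), c(1L, 1L))
  # two differences: identity 0.8, separate clusters
  c_ <- "ACGTACGTTT"
  expect_equal(sort(unique(cluster_molecule_reads(c(a, c_)))), c(1L, 2L))
})

test_that("reads from two rearrangements under one molecule key split in two", {
  ref <- build_toy_reference(4, 3, chains = "TRB", seed = 10)
  cfg <- sim_config(n_cells = 2, clone_size_weights = c("1" = 1),
                    tra_prob = 0, per_base_error_rate = 0, seed = 11)
  truth <- simulate_repertoire(ref, cfg)
  seqs <- substr(truth$chains$full_seq, 1, 150)
  # direct alignment confirms the two rearrangements are below threshold
  expect_lt(trekr:::pairwise_identity(seqs[1], seqs[2]), 0.9)
  cl <- cluster_molecule_reads(c(rep(seqs[1], 4), rep(seqs[2], 2)))
  expect_equal(cl, c(rep(1L, 4), rep(2L, 2)))
})

test_that("higher-quality seeds found clusters first", {
  a <- "ACGTACGTAC"
  b <- "TTTTTTTTTT"
  cl <- cluster_molecule_reads(c(a, a, b), mean_quality = c(10, 10, 39))
  # b is processed first but relabelling makes the biggest cluster 1
  expect_equal(cl, c(1L, 1L, 2L))
})

test_that("dominance filter implements the 50% + doubling rule", {
  expect_true(dominance_filter(c(6, 3)))   # 6/9 >= .5 and 6 >= 2*3
  expect_false(dominance_filter(c(5, 4)))  # 5 < 8
  expect_true(dominance_filter(c(4)))      # single cluster always dominant
  expect_false(dominance_filter(c(2, 2)))
  expect_false(dominance_filter(integer(0)))
  # permutation of the tail leaves the decision unchanged
  expect_identical(dominance_filter(c(8, 2, 1, 1)),
                   dominance_filter(c(8, 1, 2, 1)))
})

test_that("consensus of identical reads is the read itself, needing >= 3", {
  for (k in 3:6) {
    expect_equal(build_consensus(rep("ACGTACGTACGT", k)), "ACGTACGTACGT")
  }
  expect_null(build_consensus(rep("ACGTACGTACGT", 2)))
})

test_that("an exact 2/2 plurality tie is called N", {
  # four reads split 2/2 at position 5
  reads <- c("ACGTAACGTACG", "ACGTAACGTACG", "ACGTCACGTACG", "ACGTCACGTACG")
  cons <- build_consensus(reads)
  expect_equal(cons, "ACGTNACGTACG")
  # 3/1 majority is called normally (support 0.75 >= 0.5)
  cons2 <- build_consensus(c(reads[1], reads[1], reads[1], reads[3]))
  expect_equal(cons2, "ACGTAACGTACG")
})

test_that("leading and trailing N calls are stripped", {
  reads <- c("AACGTACGTACG", "CACGTACGTACG", "GACGTACGTACG", "TACGTACGTACG")
  # position 1 has a four-way tie -> N -> stripped
  expect_equal(build_consensus(reads), "ACGTACGTACG")
})

test_that("a dropped-out member contributes end gaps, honouring max_gap_freq", {
  # two of five reads are truncated; the tail columns have gap freq 0.4
  # (<= 0.5) and are kept with plurality calls from the three full reads
  full <- "ACGTACGTACGTACG"
  cut_ <- "ACGTACGTAC"
  cons <- build_consensus(c(full, full, full, cut_, cut_))
  expect_equal(cons, full)
  # three of five truncated: gap freq 0.6 > 0.5, tail columns dropped
  cons2 <- build_consensus(c(full, full, cut_, cut_, cut_))
  expect_equal(cons2, cut_)
})

test_that("simulated noisy molecules give near-perfect consensus", {
  withr::with_seed(500, {
    truth_seq <- random_dna_str(120)
    n_exact <- 0
    n_mol <- 150
    for (i in seq_len(n_mol)) {
      reads <- vapply(1:6, function(j) {
        chars <- strsplit(truth_seq, "")[[1]]
        hits <- which(runif(120) < 0.01)
        for (p in hits) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                   chars[p]), 1)
        paste(chars, collapse = "")
      }, character(1))
      if (identical(build_consensus(reads), truth_seq)) n_exact <- n_exact + 1
    }
    expect_gte(n_exact / n_mol, 0.99)
  })
})

test_that("per-molecule pipeline conserves molecules across outcomes", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 2)
  cfg <- sim_config(n_cells = 15, swap_rate = 0.15, reads_per_molecule = 4,
                    tra_prob = 0, seed = 33)
  truth <- simulate_repertoire(ref, cfg)
  paths <- simulate_reads(truth, ref, cfg, file.path(withr::local_tempdir(), "c"))
  reads <- parse_trekseq(paths$r1, paths$tcr)
  out <- correct_reads(reads, load_whitelist(paths$whitelist))
  cons <- call_consensus_molecules(out)
  log <- molecule_log(cons)
  expect_equal(nrow(cons), sum(log$outcome == "consensus"))
  expect_equal(nrow(log),
               nrow(unique(out[, c("corrected_barcode", "corrected_umi")])))
  expect_true(all(log$outcome %in% c("consensus", "dominance_rejected",
                                     "min_reads_rejected")))
  expect_true(all(cons$n_reads >= 3))
  expect_true(all(cons$fraction_of_molecule > 0 &
                    cons$fraction_of_molecule <= 1))
})
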