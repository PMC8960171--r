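make_cfg <- function(...) sim_config(..., seed = 101)

test_that("clone-size weights shape the simulated repertoire", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 1)
  t1 <- simulate_repertoire(ref, make_cfg(n_cells = 10,
                                          clone_size_weights = c("1" = 1)))
  expect_equal(nrow(t1$clonotypes), 10)
  expect_true(all(t1$clonotypes$size == 1))

  t5 <- simulate_repertoire(ref, make_cfg(n_cells = 10,
                                          clone_size_weights = c("5" = 1)))
  expect_equal(t5$clonotypes$size, c(5L, 5L))
})

test_that("realized clone-size histogram matches a direct draw with the same RNG", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 1)
  cfg <- sim_config(n_cells = 200, clone_size_weights = c("1" = 0.5, "10" = 0.5),
                    seed = 77)
  truth <- simulate_repertoire(ref, cfg)
  direct <- withr::with_seed(77, trekr:::draw_clone_sizes(cfg$clone_size_weights, 200))
  expect_equal(truth$clonotypes$size, direct)
  expect_equal(sum(truth$clonotypes$size), 200)
})

test_that("cells of one clonotype share identical V/J/CDR3", {
  ref <- build_toy_reference(3, 3, seed = 2)
  truth <- simulate_repertoire(ref, make_cfg(n_cells = 40))
  per_ct <- split(truth$chains[truth$chains$chain == "TRB", ],
                  truth$chains$clonotype_id[truth$chains$chain == "TRB"])
  for (ct in per_ct) {
    expect_equal(length(unique(paste(ct$v_id, ct$j_id, ct$cdr3_nt))), 1)
  }
  # distinct clonotypes carry distinct TRB rearrangements
  ct_keys <- unique(paste(truth$clonotypes$v_id, truth$clonotypes$cdr3_nt))
  expect_equal(length(ct_keys), nrow(truth$clonotypes))
})

test_that("zero-error reads reproduce the rearranged sequence exactly", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 3)
  cfg <- sim_config(n_cells = 5, per_base_error_rate = 0,
                    barcode_error_rate = 0, swap_rate = 0,
                    tra_prob = 0, seed = 9)
  truth <- simulate_repertoire(ref, cfg)
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- simulate_reads(truth, ref, cfg, prefix)
  reads <- parse_trekseq(paths$r1, paths$tcr)
  rt <- attr(paths, "read_truth")
  joined <- merge(as.data.frame(reads), as.data.frame(rt), by = "read_id")
  truthseq <- truth$chains
  truthseq$expected <- substr(truthseq$full_seq, 1, 150)
  joined <- merge(joined, truthseq[, c("barcode", "chain", "expected")],
                  by.x = c("true_barcode", "chain"),
                  by.y = c("barcode", "chain"))
  expect_true(all(joined$tcr_seq == joined$expected))
  expect_true(all(joined$barcode == joined$true_barcode))
  expect_true(all(joined$umi == joined$true_umi))
})

test_that("record counts obey molecules x reads_per_molecule", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 3)
  cfg <- sim_config(n_cells = 1, clone_size_weights = c("1" = 1),
                    reads_per_molecule = 5, umis_per_chain = 1,
                    tra_prob = 0, seed = 4)
  truth <- simulate_repertoire(ref, cfg)
  paths <- simulate_reads(truth, ref, cfg, file.path(withr::local_tempdir(), "s"))
  reads <- parse_trekseq(paths$r1, paths$tcr)
  expect_equal(nrow(reads), 5)

  cfg2 <- sim_config(n_cells = 7, reads_per_molecule = 3, umis_per_chain = 2,
                     tra_prob = 0, seed = 4)
  truth2 <- simulate_repertoire(ref, cfg2)
  paths2 <- simulate_reads(truth2, ref, cfg2,
                           file.path(withr::local_tempdir(), "s2"))
  reads2 <- parse_trekseq(paths2$r1, paths2$tcr)
  expect_equal(nrow(reads2), nrow(truth2$chains) * 2 * 3)
})

test_that("observed mismatch fraction is consistent with the error rate", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 6)
  cfg <- sim_config(n_cells = 20, per_base_error_rate = 0.01,
                    barcode_error_rate = 0, swap_rate = 0, tra_prob = 0,
                    reads_per_molecule = 2, seed = 8)
  truth <- simulate_repertoire(ref, cfg)
  paths <- simulate_reads(truth, ref, cfg, file.path(withr::local_tempdir(), "e"))
  reads <- parse_trekseq(paths$r1, paths$tcr)
  rt <- attr(paths, "read_truth")
  total_bases <- sum(nchar(reads$tcr_seq))
  total_errors <- sum(rt$n_seq_errors)
  p_hat <- total_errors / total_bases
  se <- sqrt(0.01 * 0.99 / total_bases)
  expect_lt(abs(p_hat - 0.01), 3 * se)
  # error positions carry the low quality score
  expect_equal(sum(vapply(reads$quals, function(q) sum(q == cfg$quality_low),
                          integer(1))),
               total_errors)
})

test_that("simulation is deterministic given the seed", {
  ref <- build_toy_reference(2, 2, seed = 3)
  cfg <- sim_config(n_cells = 8, seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulate_reads(simulate_repertoire(ref, cfg), ref, cfg,
                       file.path(d1, "a"))
  p2 <- simulate_reads(simulate_repertoire(ref, cfg), ref, cfg,
                       file.path(d2, "a"))
  expect_identical(readLines(p1$tcr), readLines(p2$tcr))
  expect_identical(readLines(p1$r1), readLines(p2$r1))
  expect_identical(readLines(p1$whitelist), readLines(p2$whitelist))
  expect_identical(readLines(p1$truth_reads), readLines(p2$truth_reads))
})

test_that("every read id resolves to exactly one truth record", {
  ref <- build_toy_reference(2, 2, seed = 3)
  cfg <- sim_config(n_cells = 6, seed = 22)
  truth <- simulate_repertoire(ref, cfg)
  paths <- simulate_reads(truth, ref, cfg, file.path(withr::local_tempdir(), "t"))
  reads <- parse_trekseq(paths$r1, paths$tcr)
  rt <- attr(paths, "read_truth")
  expect_equal(sort(reads$read_id), sort(rt$read_id))
  expect_equal(anyDuplicated(rt$read_id), 0L)
})

test_that("whitelist decoys keep all members at Hamming distance >= 3", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 3)
  cfg <- sim_config(n_cells = 10, n_decoys = 20, tra_prob = 0, seed = 5)
  truth <- simulate_repertoire(ref, cfg)
  paths <- simulate_reads(truth, ref, cfg, file.path(withr::local_tempdir(), "w"))
  wl <- readLines(paths$whitelist)
  decoys <- setdiff(wl, truth$cells$barcode)
  expect_equal(length(decoys), 20)
  for (d in decoys) {
    expect_true(all(trekr:::hamming_vec(d, setdiff(wl, d)) >= 3))
  }
})

test_that("sim_config validates rates and weights", {
  expect_error(sim_config(seed = 1, swap_rate = 1.5), "rates")
  expect_error(sim_config(seed = 1, clone_size_weights = c("1" = 0.7)), "sum")
  expect_error(sim_config(), "seed")
})
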