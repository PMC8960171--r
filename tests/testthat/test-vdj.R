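cons_tbl <- function(seqs, barcodes = NULL, umis = NULL, n_reads = 5L) {
  tibble::tibble(
    barcode = barcodes %||% sprintf("BC%03d", seq_along(seqs)),
    umi = umis %||% sprintf("UMI%03d", seq_along(seqs)),
    sequence = seqs, n_reads = n_reads
  )
}

test_that("error-free consensus sequences recover truth V/J/CDR3 exactly", {
  for (sd in 1:3) {
    ref <- build_toy_reference(4, 3, seed = sd)
    cfg <- sim_config(n_cells = 15, per_base_error_rate = 0,
                      barcode_error_rate = 0, swap_rate = 0, seed = sd + 100)
    truth <- simulate_repertoire(ref, cfg)
    cons <- cons_tbl(substr(truth$chains$full_seq, 1, 150),
                     barcodes = truth$chains$barcode)
    asn <- assign_vdj(cons, ref)
    expect_equal(nrow(asn), nrow(truth$chains))
    expect_equal(asn$v_call, truth$chains$v_id)
    expect_equal(asn$j_call, truth$chains$j_id)
    expect_equal(asn$cdr3_nt, truth$chains$cdr3_nt)
    expect_equal(asn$chain, truth$chains$chain)
  }
})

test_that("random DNA is rejected as unassignable", {
  ref <- build_toy_reference(3, 3, seed = 5)
  withr::with_seed(600, {
    rand <- vapply(1:10, function(i) random_dna_str(130), character(1))
  })
  asn <- assign_vdj(cons_tbl(rand), ref)
  expect_equal(nrow(asn), 0)
})

test_that("the productive flag agrees with a direct translation check", {
  ref <- build_toy_reference(3, 3, seed = 6)
  cfg <- sim_config(n_cells = 30, per_base_error_rate = 0, tra_prob = 0,
                    barcode_error_rate = 0, swap_rate = 0, seed = 61)
  truth <- simulate_repertoire(ref, cfg)
  asn <- assign_vdj(cons_tbl(substr(truth$chains$full_seq, 1, 150)), ref)
  expect_gt(nrow(asn), 0)
  for (i in seq_len(nrow(asn))) {
    cdr3 <- asn$cdr3_nt[i]
    in_frame <- nchar(cdr3) %% 3 == 0 && !grepl("[^ACGT]", cdr3)
    direct <- in_frame && !grepl("\\*", as.character(
      Biostrings::translate(Biostrings::DNAString(cdr3))))
    expect_identical(asn$productive[i], direct)
    if (asn$productive[i]) {
      expect_identical(asn$cdr3_aa[i], as.character(
        Biostrings::translate(Biostrings::DNAString(cdr3))))
      expect_equal(nchar(cdr3) %% 3, 0)
    }
  }
})

test_that("anchors with a 5' J offset still map through the alignment", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 9,
                             j_anchor_offset = 6)
  cfg <- sim_config(n_cells = 8, per_base_error_rate = 0, tra_prob = 0,
                    barcode_error_rate = 0, swap_rate = 0, seed = 91)
  truth <- simulate_repertoire(ref, cfg)
  asn <- assign_vdj(cons_tbl(substr(truth$chains$full_seq, 1, 150),
                             barcodes = truth$chains$barcode), ref)
  joined <- merge(as.data.frame(asn), as.data.frame(truth$chains),
                  by = "barcode")
  expect_gt(nrow(joined), 0)
  expect_true(all(joined$cdr3_nt.x == joined$cdr3_nt.y))
})

test_that("per-cell selection picks the tuple with most distinct UMIs", {
  base <- tibble::tibble(
    barcode = "B1", chain = "TRB", v_call = NA, d_call = NA_character_,
    j_call = "TRBJ1", v_score = 50, j_score = 40, cdr3_aa = NA_character_,
    productive = TRUE
  )
  asn <- dplyr::bind_rows(
    dplyr::mutate(base[rep(1, 3), ], v_call = "TRBV1", cdr3_nt = "TGTAAATTT",
                  umi = c("U1", "U2", "U3"), n_reads = 4L),
    dplyr::mutate(base, v_call = "TRBV2", cdr3_nt = "TGTCCCTTT",
                  umi = "U9", n_reads = 20L)
  )
  sel <- select_cell_calls(asn)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$v_call, "TRBV1")
  expect_equal(sel$umis, 3L)
  expect_equal(sel$reads, 12L)
})

test_that("UMI ties break by total reads, then lexicographic junction", {
  base <- tibble::tibble(
    barcode = "B1", chain = "TRB", d_call = NA_character_,
    j_call = "TRBJ1", v_score = 50, j_score = 40, cdr3_aa = NA_character_,
    productive = TRUE
  )
  asn <- dplyr::bind_rows(
    dplyr::mutate(base[rep(1, 2), ], v_call = "TRBV1", cdr3_nt = "TGTAAATTT",
                  umi = c("U1", "U2"), n_reads = c(4L, 3L)),   # 7 reads
    dplyr::mutate(base[rep(1, 2), ], v_call = "TRBV2", cdr3_nt = "TGTCCCTTT",
                  umi = c("U3", "U4"), n_reads = c(3L, 2L))    # 5 reads
  )
  sel <- select_cell_calls(asn)
  expect_equal(sel$v_call, "TRBV1")

  # equal reads too: lexicographically smallest junction wins
  asn2 <- dplyr::bind_rows(
    dplyr::mutate(base, v_call = "TRBV1", cdr3_nt = "TGTCCCTTT",
                  umi = "U1", n_reads = 5L),
    dplyr::mutate(base, v_call = "TRBV2", cdr3_nt = "TGTAAATTT",
                  umi = "U2", n_reads = 5L)
  )
  expect_equal(select_cell_calls(asn2)$cdr3_nt, "TGTAAATTT")
})

test_that("a TRA-only cell yields a CellTcr with only the TRA chain", {
  asn <- tibble::tibble(
    barcode = "B7", umi = "U1", chain = "TRA", v_call = "TRAV1",
    d_call = NA_character_, j_call = "TRAJ1", v_score = 40, j_score = 30,
    cdr3_nt = "TGTGGGTTT", cdr3_aa = "CGF", productive = TRUE, n_reads = 3L
  )
  sel <- select_cell_calls(asn)
  expect_equal(sel$chain, "TRA")
  expect_equal(nrow(sel), 1)
})
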