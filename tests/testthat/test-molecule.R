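wl_of <- function(...) structure(c(...), class = "trek_whitelist")

test_that("barcode correction follows the one-mismatch whitelist rule", {
  a16 <- strrep("A", 16)
  wl <- wl_of(a16, strrep("G", 16))
  # exact member
  expect_equal(correct_barcode(a16, wl), a16)
  # unique neighbour at distance 1
  expect_equal(correct_barcode(paste0(strrep("A", 15), "C"), wl), a16)
  # two whitelist neighbours at distance 1 -> ambiguous, no rescue
  wl2 <- wl_of(a16, paste0(strrep("A", 15), "G"))
  expect_true(is.na(correct_barcode(paste0(strrep("A", 15), "C"), wl2)))
  # too far
  expect_true(is.na(correct_barcode(strrep("T", 16), wl)))
  # one N is a mismatch and can be rescued; two cannot
  expect_equal(correct_barcode(paste0(strrep("A", 15), "N"), wl), a16)
  expect_true(is.na(correct_barcode(paste0(strrep("A", 14), "NN"), wl)))
})

test_that("barcode correction equals the brute-force whitelist scan", {
  set.seed(401)
  wl <- unique(replicate(40, random_dna_str(16)))
  wlo <- wl_of(wl)
  for (i in 1:400) {
    bc <- if (runif(1) < 0.5) {
      b <- sample(wl, 1)
      n_mut <- sample(0:2, 1)
      for (k in seq_len(n_mut)) {
        p <- sample(16, 1)
        substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      b
    } else random_dna_str(16)
    expect_identical(correct_barcode(bc, wlo),
                     brute_correct_barcode(bc, wl))
  }
})

test_that("UMI clustering merges single-mismatch components", {
  u1 <- strrep("A", 12)
  u2 <- paste0(strrep("A", 11), "T")
  m <- cluster_umis(setNames(c(5L, 1L), c(u1, u2)))
  expect_equal(unname(m[u1]), u1)
  expect_equal(unname(m[u2]), u1)

  far <- paste0(strrep("A", 9), "TTT")
  m2 <- cluster_umis(setNames(c(2L, 2L), c(u1, far)))
  expect_equal(unname(m2[u1]), u1)
  expect_equal(unname(m2[far]), far)
})

test_that("single-linkage chains collapse to the highest-count representative", {
  a <- strrep("A", 12)
  b <- paste0(strrep("A", 11), "C")                 # d(a,b) = 1
  c_ <- paste0(strrep("A", 10), "GC")               # d(b,c) = 1, d(a,c) = 2
  m <- cluster_umis(setNames(c(3L, 1L, 2L), c(a, b, c_)))
  expect_true(all(m == a))
  expect_identical(m, brute_umi_components(setNames(c(3L, 1L, 2L),
                                                    c(a, b, c_))))
})

test_that("UMI clustering matches brute-force graph components and is idempotent", {
  set.seed(402)
  for (rep in 1:25) {
    base <- replicate(sample(2:5, 1), random_dna_str(8))
    umis <- unique(unlist(lapply(base, function(b) {
      c(b, replicate(sample(0:2, 1), {
        p <- sample(8, 1)
        bb <- b
        substr(bb, p, p) <- sample(c("A", "C", "G", "T"), 1)
        bb
      }))
    })))
    counts <- setNames(sample(1:9, length(umis), replace = TRUE), umis)
    m <- cluster_umis(counts)
    expect_identical(m, brute_umi_components(counts))
    # idempotence: clustering the representatives changes nothing
    reps <- unique(unname(m))
    m2 <- cluster_umis(setNames(rep(1L, length(reps)), reps))
    expect_true(all(vapply(reps, function(r) m2[[r]] == r, logical(1))))
  }
})

test_that("mean-quality filter uses a strict < threshold", {
  expect_false(quality_filter(list(rep(24, 10)))) # mean 24 -> discard
  expect_true(quality_filter(list(rep(25, 10))))  # boundary kept
  expect_true(quality_filter(list(c(20, 30))))    # mean exactly 25
  expect_false(quality_filter(list(c(20, 29))))
  expect_error(quality_filter(list(integer(0))), "empty")
})

test_that("filter log conserves reads and attributes losses to single causes", {
  d <- withr::local_tempdir()
  a16 <- strrep("A", 16); g16 <- strrep("G", 16)
  wl <- wl_of(a16, g16, paste0(strrep("A", 15), "G"))
  ids <- sprintf("r%d", 1:5)
  r1 <- c(paste0(a16, strrep("T", 12)),                       # exact
          paste0(strrep("A", 15), "C", strrep("T", 12)),      # ambiguous
          paste0(g16, strrep("T", 12)),                       # exact, low qual
          paste0(strrep("T", 16), strrep("T", 12)),           # no match
          paste0(g16, strrep("T", 12)))                       # exact
  quals <- c("IIII", "IIII", "####", "IIII", "IIII")
  writeLines(paste0("@", ids, "\n", r1, "\n+\n", strrep("I", 28)),
             file.path(d, "r1.fastq"))
  writeLines(paste0("@", ids, "\n", "ACGT", "\n+\n", quals),
             file.path(d, "tcr.fastq"))
  reads <- parse_trekseq(file.path(d, "r1.fastq"), file.path(d, "tcr.fastq"))
  out <- correct_reads(reads, wl)
  log <- filter_log(out)
  expect_equal(sum(log$n[log$reason != "retained"]) +
                 log$n[log$reason == "retained"], 5)
  expect_equal(log$n[log$reason == "ambiguous_barcode"], 1)
  expect_equal(log$n[log$reason == "no_whitelist_match"], 1)
  expect_equal(log$n[log$reason == "low_quality"], 1)
  expect_equal(nrow(out), 2)
})

test_that("non-swapped simulated reads always recover their true barcode", {
  ref <- build_toy_reference(2, 2, chains = "TRB", seed = 1)
  cfg <- sim_config(n_cells = 25, barcode_error_rate = 0.3, swap_rate = 0.1,
                    per_base_error_rate = 0, tra_prob = 0, seed = 31)
  truth <- simulate_repertoire(ref, cfg)
  paths <- simulate_reads(truth, ref, cfg, file.path(withr::local_tempdir(), "b"))
  reads <- parse_trekseq(paths$r1, paths$tcr)
  wl <- load_whitelist(paths$whitelist)
  out <- correct_reads(reads, wl)
  rt <- attr(paths, "read_truth")
  joined <- merge(as.data.frame(out[, c("read_id", "corrected_barcode")]),
                  as.data.frame(rt), by = "read_id")
  ns <- joined[!joined$swapped, ]
  expect_equal(mean(ns$corrected_barcode == ns$true_barcode), 1)
})
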