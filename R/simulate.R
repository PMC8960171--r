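#' Simulation configuration
#'
#' Bundles every knob of the read simulator. Clone sizes are drawn from
#' `clone_size_weights`, a named numeric vector mapping clone size (number
#' of cells) to probability; sizes are drawn until the requested number of
#' cells is reached, truncating the final clone to fit.
#'
#' @param n_cells Number of cells to simulate.
#' @param clone_size_weights Named probability vector over clone sizes,
#'   e.g. `c("1" = 0.5, "10" = 0.5)`. Must sum to 1.
#' @param reads_per_molecule Reads emitted per (cell, chain, UMI) molecule.
#' @param umis_per_chain Distinct UMIs (mRNA molecules) per cell and chain.
#' @param per_base_error_rate Per-base substitution error rate on the TCR read.
#' @param indel_rate Per-base indel rate on the TCR read (default 0; the
#'   default error model is substitution-only).
#' @param barcode_error_rate Fraction of reads whose observed barcode carries
#'   one substitution.
#' @param umi_error_rate Fraction of reads whose observed UMI carries one
#'   substitution.
#' @param swap_rate Fraction of reads reassigned to another cell's barcode
#'   (barcode swapping / chimera model).
#' @param tra_prob Probability that a cell's TRA chain is captured at all
#'   (TRB is always present).
#' @param quality_high,quality_low Phred scores given to correct and
#'   erroneous TCR-read bases, respectively.
#' @param n_decoys Extra whitelist barcodes (Hamming distance >= 3 from all
#'   true barcodes and from each other) emulating unobserved whitelist
#'   entries.
#' @param seed Integer seed; required.
#' @return A validated list of class `trek_sim_config`.
#' @export
sim_config <- function(n_cells = 100,
                       clone_size_weights = c("1" = 0.5, "10" = 0.5),
                       reads_per_molecule = 5,
                       umis_per_chain = 3,
                       per_base_error_rate = 0.005,
                       indel_rate = 0,
                       barcode_error_rate = 0.02,
                       umi_error_rate = 0,
                       swap_rate = 0.01,
                       tra_prob = 0.75,
                       quality_high = 37,
                       quality_low = 11,
                       n_decoys = 50,
                       seed = NULL) {
  if (is.null(seed)) abort("`seed` is required in sim_config()")
  rates <- c(per_base_error_rate, indel_rate, barcode_error_rate,
             umi_error_rate, swap_rate, tra_prob)
  if (any(rates < 0 | rates > 1)) abort("all rates must be in [0, 1]")
  w <- as.numeric(clone_size_weights)
  if (is.null(names(clone_size_weights)) ||
      anyNA(suppressWarnings(as.integer(names(clone_size_weights))))) {
    abort("clone_size_weights must be named by integer clone sizes")
  }
  if (abs(sum(w) - 1) > 1e-9) abort("clone_size_weights must sum to 1")
  stopifnot(n_cells >= 1, reads_per_molecule >= 1, umis_per_chain >= 1,
            quality_high >= 0, quality_high <= 60,
            quality_low >= 0, quality_low <= 60)
  structure(list(
    n_cells = as.integer(n_cells),
    clone_size_weights = clone_size_weights,
    reads_per_molecule = as.integer(reads_per_molecule),
    umis_per_chain = as.integer(umis_per_chain),
    per_base_error_rate = per_base_error_rate,
    indel_rate = indel_rate,
    barcode_error_rate = barcode_error_rate,
    umi_error_rate = umi_error_rate,
    swap_rate = swap_rate,
    tra_prob = tra_prob,
    quality_high = as.integer(quality_high),
    quality_low = as.integer(quality_low),
    n_decoys = as.integer(n_decoys),
    seed = as.integer(seed)
  ), class = "trek_sim_config")
}

#' Simulate a clonally structured TCR repertoire
#'
#' Draws clone sizes from the configured weights, assigns each clone a TRB
#' rearrangement (random V + 0-10 nt junction insert + random J, joined at
#' the conserved anchors so the true CDR3 is the Cys codon through the
#' Phe/Trp codon) and, with probability `tra_prob` per cell, a clone-shared
#' TRA rearrangement. Cells in one clonotype share identical V/J/CDR3.
#'
#' @param ref A `trek_reference` containing TRB (and optionally TRA) V and J
#'   segments.
#' @param cfg A [sim_config()].
#' @return A list of class `trek_truth` with elements `cells` (tibble:
#'   `barcode`, `clonotype_id`, `cell_type`, `sample_id`), `chains` (tibble:
#'   `barcode`, `chain`, `v_id`, `j_id`, `cdr3_nt`, `full_seq`,
#'   `clonotype_id`) and `clonotypes` (tibble: `clonotype_id`, `size`,
#'   `v_id`, `j_id`, `cdr3_nt`).
#' @export
simulate_repertoire <- function(ref, cfg) {
  stopifnot(inherits(cfg, "trek_sim_config"))
  validate_reference(ref)
  if (!any(ref$chain == "TRB" & ref$kind == "V") ||
      !any(ref$chain == "TRB" & ref$kind == "J")) {
    abort("reference must contain TRB V and J segments")
  }
  withr::with_seed(cfg$seed, {
    sizes <- draw_clone_sizes(cfg$clone_size_weights, cfg$n_cells)
    n_clones <- length(sizes)

    rearr <- function(chain) {
      v <- ref[ref$chain == chain & ref$kind == "V", ]
      j <- ref[ref$chain == chain & ref$kind == "J", ]
      vi <- v[sample.int(nrow(v), 1), ]
      ji <- j[sample.int(nrow(j), 1), ]
      ins <- random_dna(sample(0:10, 1))
      # V through its Cys codon + insert + J from its anchor onward
      v_part <- substr(vi$sequence, 1, vi$anchor + 3)
      j_part <- substr(ji$sequence, ji$anchor + 1, nchar(ji$sequence))
      cdr3 <- paste0(substr(vi$sequence, vi$anchor + 1, vi$anchor + 3),
                     ins, substr(ji$sequence, ji$anchor + 1, ji$anchor + 3))
      tibble(v_id = vi$segment_id, j_id = ji$segment_id,
             cdr3_nt = cdr3, full_seq = paste0(v_part, ins, j_part))
    }

    # distinct clonotypes must carry distinct TRB rearrangements, otherwise
    # the ground-truth partition is not recoverable even in principle
    seen <- character(0)
    clono <- purrr::map_dfr(seq_len(n_clones), function(i) {
      r <- rearr("TRB")
      while (paste(r$v_id, r$cdr3_nt) %in% seen) r <- rearr("TRB")
      seen <<- c(seen, paste(r$v_id, r$cdr3_nt))
      dplyr::mutate(r, clonotype_id = sprintf("CT%04d", i), size = sizes[i])
    })
    has_tra <- any(ref$chain == "TRA" & ref$kind == "V") &&
      any(ref$chain == "TRA" & ref$kind == "J")
    tra <- if (has_tra) {
      purrr::map_dfr(seq_len(n_clones), function(i) {
        dplyr::mutate(rearr("TRA"), clonotype_id = sprintf("CT%04d", i))
      })
    } else NULL

    barcodes <- random_barcodes(cfg$n_cells)
    cells <- tibble(
      barcode = barcodes,
      clonotype_id = rep(clono$clonotype_id, clono$size),
      cell_type = "T-cell",
      sample_id = "sim"
    )
    trb_chains <- dplyr::inner_join(cells, clono, by = "clonotype_id") |>
      dplyr::transmute(.data$barcode, chain = "TRB", .data$v_id, .data$j_id,
                       .data$cdr3_nt, .data$full_seq, .data$clonotype_id)
    chains <- trb_chains
    if (has_tra && cfg$tra_prob > 0) {
      keep <- runif(nrow(cells)) < cfg$tra_prob
      tra_chains <- dplyr::inner_join(cells[keep, ], tra, by = "clonotype_id") |>
        dplyr::transmute(.data$barcode, chain = "TRA", .data$v_id, .data$j_id,
                         .data$cdr3_nt, .data$full_seq, .data$clonotype_id)
      chains <- dplyr::bind_rows(trb_chains, tra_chains) |>
        dplyr::arrange(.data$barcode, .data$chain)
    }
    structure(list(cells = cells, chains = chains,
                   clonotypes = clono[, c("clonotype_id", "size", "v_id",
                                          "j_id", "cdr3_nt")]),
              class = "trek_truth")
  })
}

## draw clone sizes until the cell budget is reached; truncate the last clone
draw_clone_sizes <- function(weights, n_cells) {
  size_vals <- as.integer(names(weights))
  sizes <- integer(0)
  total <- 0
  while (total < n_cells) {
    s <- size_vals[sample.int(length(size_vals), 1,
                              prob = as.numeric(weights))]
    s <- min(s, n_cells - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  sizes
}

## distinct random cell barcodes
random_barcodes <- function(n) {
  bcs <- character(0)
  while (length(bcs) < n) {
    new <- purrr::map_chr(seq_len(n - length(bcs)), ~ random_dna(BC_LEN))
    bcs <- unique(c(bcs, new))
  }
  bcs[seq_len(n)]
}

#' Simulate TREK-seq FASTQ files from a repertoire
#'
#' Emits the two-read structure of a 3' TCR enrichment library: Read 1 is the
#' 28 nt cell barcode + UMI (16 + 12 nt, 10x 3' v3 layout) and the TCR read
#' carries up to `tcr_cycles` nt of the rearranged sequence with per-base
#' Phred qualities. Each (cell, chain, UMI) molecule is emitted
#' `reads_per_molecule` times; substitution errors are i.i.d. per base at
#' `per_base_error_rate` (erroneous bases get `quality_low`); a `swap_rate`
#' fraction of reads is reassigned to another cell's barcode, and a
#' `barcode_error_rate` fraction carries one barcode substitution.
#' Also writes the matching barcode whitelist (true barcodes plus decoys at
#' Hamming distance >= 3, so 1-mismatch correction is uniquely resolvable)
#' and ground-truth tables.
#'
#' @param truth A `trek_truth` from [simulate_repertoire()].
#' @param ref The `trek_reference` used to build it.
#' @param cfg The same [sim_config()].
#' @param out_prefix Path prefix for the outputs.
#' @param tcr_cycles TCR read length cap in cycles (default 150).
#' @return Named list of paths: `r1`, `tcr` (gzipped FASTQs), `whitelist`,
#'   `truth_cells`, `truth_chains`, `truth_reads` (TSVs), plus the
#'   `read_truth` tibble invisibly attached as attribute `"read_truth"`.
#' @export
simulate_reads <- function(truth, ref, cfg, out_prefix, tcr_cycles = 150) {
  stopifnot(inherits(truth, "trek_truth"), inherits(cfg, "trek_sim_config"))
  if (nrow(truth$chains) == 0) abort("truth contains no rearrangements")

  withr::with_seed(cfg$seed + 1L, {
    mol <- truth$chains |>
      dplyr::slice(rep(seq_len(dplyr::n()), each = cfg$umis_per_chain)) |>
      dplyr::mutate(umi = purrr::map_chr(seq_len(dplyr::n()),
                                         ~ random_dna(UMI_LEN)),
                    molecule_id = seq_len(dplyr::n()))

    reads <- mol |>
      dplyr::slice(rep(seq_len(dplyr::n()), each = cfg$reads_per_molecule)) |>
      dplyr::mutate(read_id = sprintf("read%07d", seq_len(dplyr::n())))

    n <- nrow(reads)
    seqs <- substr(reads$full_seq, 1, tcr_cycles)

    # substitution errors with low quality at error positions
    err <- mutate_seqs(seqs, cfg$per_base_error_rate, cfg$indel_rate,
                       cfg$quality_high, cfg$quality_low)

    # barcode swapping: reassign to a different cell's true barcode
    swapped <- runif(n) < cfg$swap_rate & nrow(truth$cells) > 1
    obs_bc <- reads$barcode
    if (any(swapped)) {
      obs_bc[swapped] <- purrr::map_chr(reads$barcode[swapped], function(b) {
        sample(setdiff(truth$cells$barcode, b), 1)
      })
    }
    # one barcode substitution on a fraction of reads
    bc_err <- runif(n) < cfg$barcode_error_rate
    obs_bc[bc_err] <- purrr::map_chr(obs_bc[bc_err], mutate_one_base)
    obs_umi <- reads$umi
    umi_err <- runif(n) < cfg$umi_error_rate
    obs_umi[umi_err] <- purrr::map_chr(obs_umi[umi_err], mutate_one_base)

    paths <- list(
      r1 = paste0(out_prefix, "_R1.fastq.gz"),
      tcr = paste0(out_prefix, "_TCR.fastq.gz"),
      whitelist = paste0(out_prefix, "_whitelist.txt"),
      truth_cells = paste0(out_prefix, "_truth_cells.tsv"),
      truth_chains = paste0(out_prefix, "_truth_chains.tsv"),
      truth_reads = paste0(out_prefix, "_truth_reads.tsv")
    )

    r1_seq <- paste0(obs_bc, obs_umi)
    r1_qual <- strrep(phred_char(cfg$quality_high), R1_LEN)
    write_fastq_gz(paths$r1, reads$read_id, r1_seq, r1_qual)
    write_fastq_gz(paths$tcr, reads$read_id, err$seq, err$qual)

    wl <- c(truth$cells$barcode,
            decoy_barcodes(truth$cells$barcode, cfg$n_decoys))
    writeLines(wl, paths$whitelist)

    read_truth <- tibble(
      read_id = reads$read_id,
      true_barcode = reads$barcode,
      true_umi = reads$umi,
      chain = reads$chain,
      molecule_id = reads$molecule_id,
      n_seq_errors = err$n_errors,
      swapped = swapped,
      barcode_errored = bc_err
    )
    readr::write_tsv(truth$cells, paths$truth_cells)
    readr::write_tsv(truth$chains |> dplyr::select(-"full_seq"),
                     paths$truth_chains)
    readr::write_tsv(read_truth, paths$truth_reads)
    attr(paths, "read_truth") <- read_truth
    paths
  })
}

## substitution (+ optional indel) errors; returns sequences, quality
## strings, and per-read error counts
mutate_seqs <- function(seqs, sub_rate, indel_rate, q_high, q_low) {
  n_err <- integer(length(seqs))
  out_seq <- character(length(seqs))
  out_qual <- character(length(seqs))
  qh <- phred_char(q_high); ql <- phred_char(q_low)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    L <- length(chars)
    quals <- rep(qh, L)
    if (sub_rate > 0) {
      hits <- which(runif(L) < sub_rate)
      for (p in hits) {
        chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
        quals[p] <- ql
      }
      n_err[i] <- length(hits)
    }
    if (indel_rate > 0) {
      pos <- which(runif(length(chars)) < indel_rate)
      for (p in rev(pos)) {
        if (runif(1) < 0.5) { # deletion
          chars <- chars[-p]; quals <- quals[-p]
        } else {              # insertion
          chars <- append(chars, sample(DNA_BASES, 1), after = p)
          quals <- append(quals, ql, after = p)
        }
        n_err[i] <- n_err[i] + 1L
      }
    }
    out_seq[i] <- paste(chars, collapse = "")
    out_qual[i] <- paste(quals, collapse = "")
  }
  list(seq = out_seq, qual = out_qual, n_errors = n_err)
}

mutate_one_base <- function(s) {
  p <- sample.int(nchar(s), 1)
  b <- sample(setdiff(DNA_BASES, substr(s, p, p)), 1)
  paste0(substr(s, 1, p - 1), b, substr(s, p + 1, nchar(s)))
}

phred_char <- function(q) rawToChar(as.raw(q + 33L))

write_fastq_gz <- function(path, ids, seqs, quals) {
  if (length(quals) == 1) quals <- rep(quals, length(ids))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n", quals)
  writeLines(rec, con)
  invisible(path)
}

## decoys at Hamming distance >= 3 from all accepted whitelist members
decoy_barcodes <- function(true_bcs, n_decoys) {
  if (n_decoys == 0) return(character(0))
  all_bcs <- true_bcs
  decoys <- character(0)
  while (length(decoys) < n_decoys) {
    cand <- random_dna(BC_LEN)
    if (all(hamming_vec(cand, all_bcs) >= 3)) {
      decoys <- c(decoys, cand)
      all_bcs <- c(all_bcs, cand)
    }
  }
  decoys
}

## Hamming distance between one string and a vector of equal-length strings
hamming_vec <- function(s, v) {
  a <- utf8ToInt(s)
  vapply(v, function(x) sum(utf8ToInt(x) != a), integer(1), USE.NAMES = FALSE)
}
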