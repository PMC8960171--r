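#' Build a toy V/J segment reference
#'
#' Generates a small synthetic V(D)J segment reference suitable for testing
#' the reconstruction workflow end to end.  Every V segment ends in a
#' conserved cysteine codon (`TGT`/`TGC`) at its anchor position and every J
#' segment carries a conserved phenylalanine/tryptophan codon
#' (`TTT`/`TTC`/`TGG`) at its anchor, followed by a fixed framework-4-like
#' motif, mirroring the IMGT junction convention (Cys104 ... Phe/Trp118).
#' Segments are rejection-sampled so that no two share 90% or more pairwise
#' identity, which keeps segment assignment unambiguous by construction.
#'
#' This reference is synthetic: it stands in for a curated germline segment
#' database (e.g. IMGT) in tests and simulations, and makes the true CDR3 of
#' every simulated rearrangement well defined.
#'
#' @param n_v,n_j Number of V and J segments per chain (each >= 2).
#' @param chains Character vector of chains to build, subset of
#'   `c("TRA", "TRB")`.
#' @param seed Integer seed; required so that references are reproducible.
#' @param v_length,j_tail_length Length of each V segment and of the J
#'   sequence 3' of (and including) the anchor codon, in nucleotides.
#' @param j_anchor_offset Number of J nucleotides 5' of the anchor codon
#'   (default 0: the anchor codon opens the segment). Simulated
#'   rearrangements use the J from its anchor onward, so any 5' offset
#'   bases never appear in reads; the default keeps the toy germline free
#'   of read-absent sequence, which keeps local alignments — and therefore
#'   the truth CDR3 — unambiguous.
#'
#' @return A tibble of class `trek_reference` with columns `segment_id`,
#'   `chain` (`"TRA"`/`"TRB"`), `kind` (`"V"`/`"J"`), `sequence` and
#'   `anchor` (0-based position of the first base of the conserved codon).
#' @examples
#' ref <- build_toy_reference(2, 2, chains = "TRB", seed = 7)
#' ref
#' @export
build_toy_reference <- function(n_v, n_j, chains = c("TRA", "TRB"), seed,
                                v_length = 84, j_tail_length = 45,
                                j_anchor_offset = 0) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: reference construction must be reproducible.")
  }
  stopifnot(n_v >= 2, n_j >= 2, v_length %% 3 == 0)
  chains <- match.arg(chains, c("TRA", "TRB"), several.ok = TRUE)

  withr::with_seed(seed, {
    segs <- purrr::map_dfr(chains, function(ch) {
      vs <- purrr::map_chr(seq_len(n_v), function(i) {
        paste0(random_dna(v_length - 3), sample(c("TGT", "TGC"), 1))
      })
      # shared FR4-like motif after the J anchor; the 5' offset and the tail
      # beyond the motif are random so J segments stay distinguishable
      fr4 <- "GGCACCCGTCTGACCGTTCTG"
      js <- purrr::map_chr(seq_len(n_j), function(i) {
        anchor_codon <- sample(c("TTT", "TTC", "TGG"), 1)
        tail_rand <- j_tail_length - 3 - nchar(fr4)
        stopifnot(tail_rand >= 0)
        paste0(random_dna(j_anchor_offset), anchor_codon, fr4,
               random_dna(tail_rand))
      })
      tibble(
        segment_id = c(sprintf("%sV%d", ch, seq_len(n_v)),
                       sprintf("%sJ%d", ch, seq_len(n_j))),
        chain = ch,
        kind = rep(c("V", "J"), c(n_v, n_j)),
        sequence = c(vs, js),
        anchor = c(rep(v_length - 3L, n_v), rep(as.integer(j_anchor_offset), n_j))
      )
    })
    # resample any segment closer than 90% identity to an earlier one
    for (i in seq_len(nrow(segs))) {
      tries <- 0
      while (i > 1 && any(pairwise_identity(segs$sequence[i],
                                            segs$sequence[seq_len(i - 1)]) >= 0.9)) {
        segs$sequence[i] <- regenerate_segment(segs$kind[i], v_length,
                                               j_tail_length, j_anchor_offset)
        tries <- tries + 1
        if (tries > 100) abort("could not generate sufficiently distinct segments")
      }
    }
    new_reference(segs)
  })
}

regenerate_segment <- function(kind, v_length, j_tail_length, j_anchor_offset) {
  fr4 <- "GGCACCCGTCTGACCGTTCTG"
  if (kind == "V") {
    paste0(random_dna(v_length - 3), sample(c("TGT", "TGC"), 1))
  } else {
    paste0(random_dna(j_anchor_offset), sample(c("TTT", "TTC", "TGG"), 1),
           fr4, random_dna(j_tail_length - 3 - nchar(fr4)))
  }
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

new_reference <- function(df) {
  validate_reference(df)
  class(df) <- c("trek_reference", class(df))
  df
}

validate_reference <- function(df) {
  req <- c("segment_id", "chain", "kind", "sequence", "anchor")
  if (!all(req %in% names(df))) {
    abort(paste0("reference needs columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(df$segment_id)) abort("duplicate segment_id in reference")
  if (!all(df$chain %in% c("TRA", "TRB"))) abort("chain must be TRA or TRB")
  if (!all(df$kind %in% c("V", "D", "J"))) abort("kind must be V, D or J")
  if (!all(grepl("^[ACGT]+$", df$sequence))) {
    abort("reference sequences must be uppercase ACGT")
  }
  vj <- df$kind %in% c("V", "J")
  if (any(is.na(df$anchor[vj]))) abort("every V and J segment needs an anchor")
  bad <- vj & !is.na(df$anchor) &
    (df$anchor < 0 | df$anchor + 3 > nchar(df$sequence))
  if (any(bad)) {
    abort(paste0("anchor codon out of bounds for: ",
                 paste(df$segment_id[bad], collapse = ", ")))
  }
  invisible(df)
}

#' Write a segment reference as FASTA plus anchor table
#'
#' @param ref A `trek_reference` tibble.
#' @param fasta,anchors Output paths for the FASTA file and the tab-separated
#'   anchor annotation (`segment_id`, `kind`, `chain`, `anchor_0based`).
#' @return Invisibly, a named list of the two paths.
#' @export
write_segment_reference <- function(ref, fasta, anchors) {
  validate_reference(ref)
  seqs <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$segment_id))
  Biostrings::writeXStringSet(seqs, fasta)
  readr::write_tsv(
    tibble(segment_id = ref$segment_id, kind = ref$kind,
           chain = ref$chain, anchor_0based = ref$anchor),
    anchors
  )
  invisible(list(fasta = fasta, anchors = anchors))
}

#' Load a V(D)J segment reference from FASTA plus anchor table
#'
#' Reads germline segment sequences and their conserved-codon anchors.
#' IMGT-gapped sequences (containing `.` or `-`) are accepted: gaps are
#' removed and the anchor position is remapped to ungapped coordinates by
#' counting non-gap characters.
#'
#' @param fasta Path to the segment FASTA. Sequence ids must match the
#'   anchor table's `segment_id` column.
#' @param anchors Path to a TSV with columns `segment_id`, `kind`, `chain`,
#'   `anchor_0based` (anchor position in the FASTA coordinates, gapped if the
#'   FASTA is gapped; may be `NA` for D segments only).
#' @return A `trek_reference` tibble (ungapped, anchors remapped).
#' @export
load_segment_reference <- function(fasta, anchors) {
  seqs <- Biostrings::readBStringSet(fasta)
  ann <- readr::read_tsv(anchors, show_col_types = FALSE,
                         col_types = readr::cols(
                           segment_id = "c", kind = "c", chain = "c",
                           anchor_0based = "i"))
  ids <- names(seqs)
  missing <- setdiff(ids, ann$segment_id)
  if (length(missing)) {
    abort(paste0("segments missing from anchor table: ",
                 paste(missing, collapse = ", ")))
  }
  ann <- ann[match(ids, ann$segment_id), ]
  raw <- toupper(as.character(seqs))
  ungapped <- gsub("[.-]", "", raw)
  anchor <- purrr::map2_int(raw, ann$anchor_0based, function(s, a) {
    if (is.na(a)) return(NA_integer_)
    if (a >= nchar(s)) abort("anchor beyond sequence length")
    # ungapped anchor = number of non-gap characters strictly before it
    prefix <- substr(s, 1, a)
    as.integer(nchar(gsub("[.-]", "", prefix)))
  })
  vj <- ann$kind %in% c("V", "J")
  if (any(is.na(anchor[vj]))) {
    abort(paste0("missing anchor for V/J segment(s): ",
                 paste(ids[vj & is.na(anchor)], collapse = ", ")))
  }
  new_reference(tibble(
    segment_id = ids, chain = ann$chain, kind = ann$kind,
    sequence = unname(ungapped), anchor = unname(anchor)
  ))
}

## pairwise identity of one sequence against a set: matches of the
## end-gap-free global alignment over the longer sequence's length.  The
## denominator spans the whole comparison (not just the scored overlap), so
## dissimilar sequences cannot score high through a chance micro-overlap.
pairwise_identity <- function(seq, others) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(others), Biostrings::DNAString(seq),
    type = "overlap", substitutionMatrix = nuc_submat(),
    gapOpening = 2, gapExtension = 1
  )
  Biostrings::nmatch(aln) / pmax(nchar(others), nchar(seq))
}

nuc_submat <- function() {
  if (is.null(.trekr_env$submat)) {
    .trekr_env$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  }
  .trekr_env$submat
}

.trekr_env <- new.env(parent = emptyenv())
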