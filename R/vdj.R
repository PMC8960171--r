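#' V(D)J assignment parameters
#'
#' Scoring constants for the built-in local aligner used in place of a
#' germline aligner binary: match +1, mismatch -1, gap open -2, gap extend
#' -1, with a minimum alignment score (roughly the number of matched bases)
#' required for both the V and the J call.
#'
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring.
#' @param min_score Minimum V and J alignment score (default 15).
#' @param d_min_exact Minimum exact-match length for an optional D call.
#' @return List of class `trek_vdj_params`.
#' @export
vdj_params <- function(match = 1, mismatch = -1, gap_opening = 2,
                       gap_extension = 1, min_score = 15, d_min_exact = 5) {
  structure(list(match = match, mismatch = mismatch,
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 min_score = min_score, d_min_exact = as.integer(d_min_exact)),
            class = "trek_vdj_params")
}

#' Assign V/(D)/J segments and extract the CDR3 for consensus molecules
#'
#' Each consensus sequence is locally aligned against every V and J segment
#' of the reference. The best V is chosen by score (ties broken by longer
#' aligned span, then lexicographic id); the chain is the chain of the best
#' V and the best J is chosen among that chain's J segments by the same
#' rule. The assignment is rejected (row omitted) when either score falls
#' below `min_score` or when the mapped anchors are out of order on the
#' consensus. The CDR3 is the consensus interval from the codon aligned to
#' the V segment's conserved cysteine through the codon aligned to the J
#' segment's conserved phenylalanine/tryptophan (junction convention,
#' inclusive). A D call is reported only when a D segment of the chain has
#' an exact match of at least `d_min_exact` nt inside the junction.
#'
#' @param consensus Tibble from [call_consensus_molecules()] (columns
#'   `barcode`, `umi`, `sequence`, `n_reads`).
#' @param ref A `trek_reference`.
#' @param params [vdj_params()].
#' @return Tibble with one row per assignable molecule: `barcode`, `umi`,
#'   `chain`, `v_call`, `d_call`, `j_call`, `v_score`, `j_score`, `cdr3_nt`,
#'   `cdr3_aa`, `productive`, `n_reads`.
#' @export
assign_vdj <- function(consensus, ref, params = vdj_params()) {
  validate_reference(ref)
  if (nrow(ref) == 0) abort("empty segment reference")
  empty <- tibble(barcode = character(), umi = character(),
                  chain = character(), v_call = character(),
                  d_call = character(), j_call = character(),
                  v_score = numeric(), j_score = numeric(),
                  cdr3_nt = character(), cdr3_aa = character(),
                  productive = logical(), n_reads = integer())
  if (nrow(consensus) == 0) return(empty)

  vs <- ref[ref$kind == "V", ]
  js <- ref[ref$kind == "J", ]
  ds <- ref[ref$kind == "D", ]
  # align each *unique* consensus sequence once
  useq <- unique(consensus$sequence)
  seqs <- Biostrings::DNAStringSet(useq)

  # one vectorised alignment call per segment: all unique consensus vs segment
  align_all <- function(seg_tbl) {
    purrr::map(seq_len(nrow(seg_tbl)), function(i) {
      aln <- Biostrings::pairwiseAlignment(
        seqs, Biostrings::DNAString(seg_tbl$sequence[i]),
        type = "local", substitutionMatrix = nuc_submat(),
        gapOpening = params$gap_opening, gapExtension = params$gap_extension
      )
      ind <- Biostrings::nindel(aln)
      list(seg_seq = seg_tbl$sequence[i],
           score = Biostrings::score(aln),
           p_start = Biostrings::start(Biostrings::pattern(aln)),
           p_end = Biostrings::end(Biostrings::pattern(aln)),
           s_start = Biostrings::start(Biostrings::subject(aln)),
           s_end = Biostrings::end(Biostrings::subject(aln)),
           n_indel = Biostrings::insertion(ind)[, "WidthSum"] +
             Biostrings::deletion(ind)[, "WidthSum"],
           params = params)
    })
  }
  v_aln <- align_all(vs)
  j_aln <- align_all(js)

  pick_best <- function(alns, seg_tbl, m, allowed = seq_len(nrow(seg_tbl))) {
    sc <- vapply(alns, function(a) a$score[m], numeric(1))
    span <- vapply(alns, function(a) a$p_end[m] - a$p_start[m] + 1, numeric(1))
    sc[-allowed] <- -Inf
    ord <- order(-sc, -span, seg_tbl$segment_id)
    ord[1]
  }

  urows <- purrr::map(seq_along(useq), function(m) {
    bi <- pick_best(v_aln, vs, m)
    v <- v_aln[[bi]]
    if (v$score[m] < params$min_score) return(NULL)
    chain <- vs$chain[bi]
    j_allowed <- which(js$chain == chain)
    if (!length(j_allowed)) return(NULL)
    bj <- pick_best(j_aln, js, m, j_allowed)
    j <- j_aln[[bj]]
    if (j$score[m] < params$min_score) return(NULL)

    cys <- map_subject_to_pattern(v, m, vs$anchor[bi] + 1L, useq[m]) # 1-based
    phe <- map_subject_to_pattern(j, m, js$anchor[bj] + 1L, useq[m])
    if (is.na(cys) || is.na(phe)) return(NULL)
    # anchors must be ordered: Cys codon ends before Phe/Trp codon starts,
    # and the V alignment must begin before the J alignment
    if (!(cys + 2 < phe && v$p_start[m] < j$p_start[m])) return(NULL)
    cdr3_end <- phe + 2
    if (cdr3_end > nchar(useq[m]) || cys < 1) return(NULL)
    cdr3 <- substr(useq[m], cys, cdr3_end)

    productive <- is_productive(cdr3)
    cdr3_aa <- if (productive) translate_dna(cdr3) else NA_character_

    d_call <- NA_character_
    if (nrow(ds)) {
      dsc <- ds[ds$chain == chain, ]
      if (nrow(dsc)) {
        hits <- vapply(dsc$sequence, function(dseq) {
          longest_exact_match(cdr3, dseq)
        }, integer(1))
        if (any(hits >= params$d_min_exact)) {
          d_call <- dsc$segment_id[which.max(hits)]
        }
      }
    }

    tibble(chain = chain, v_call = vs$segment_id[bi], d_call = d_call,
           j_call = js$segment_id[bj], v_score = v$score[m],
           j_score = j$score[m], cdr3_nt = cdr3, cdr3_aa = cdr3_aa,
           productive = productive, sequence = useq[m])
  })
  utab <- dplyr::bind_rows(urows)
  if (nrow(utab) == 0) return(empty)
  out <- consensus |>
    dplyr::select("barcode", "umi", "sequence", "n_reads") |>
    dplyr::inner_join(utab, by = "sequence") |>
    dplyr::select("barcode", "umi", "chain", "v_call", "d_call", "j_call",
                  "v_score", "j_score", "cdr3_nt", "cdr3_aa", "productive",
                  "n_reads")
  if (nrow(out) == 0) empty else out
}

## map a subject (segment) position to a pattern (consensus) position
## through alignment m; extrapolates by offset when the anchor lies just
## outside the aligned block; NA when unmappable.  Indel-free alignments
## (the overwhelming majority) map linearly; otherwise the single alignment
## is recomputed and its gap structure walked.
map_subject_to_pattern <- function(a, m, s_pos, pattern_seq) {
  if (s_pos < a$s_start[m]) {
    p <- a$p_start[m] - (a$s_start[m] - s_pos)
    return(if (p >= 1) p else NA_integer_)
  }
  if (s_pos > a$s_end[m]) {
    return(a$p_end[m] + (s_pos - a$s_end[m]))
  }
  if (a$n_indel[m] == 0) {
    return(a$p_start[m] + (s_pos - a$s_start[m]))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern_seq), Biostrings::DNAString(a$seg_seq),
    type = "local", substitutionMatrix = nuc_submat(),
    gapOpening = a$params$gap_opening, gapExtension = a$params$gap_extension
  )
  pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sp <- a$s_start[m] - 1L
  pp <- a$p_start[m] - 1L
  for (t in seq_along(sc)) {
    if (pc[t] != "-") pp <- pp + 1L
    if (sc[t] != "-") {
      sp <- sp + 1L
      if (sp == s_pos) {
        return(if (pc[t] == "-") NA_integer_ else pp)
      }
    }
  }
  NA_integer_
}

is_productive <- function(cdr3) {
  if (is.na(cdr3) || nchar(cdr3) %% 3 != 0 || nchar(cdr3) == 0) return(FALSE)
  if (grepl("[^ACGT]", cdr3)) return(FALSE)
  aa <- translate_dna(cdr3)
  !grepl("\\*", aa)
}

translate_dna <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X"))
}

## length of the longest exact substring of `d` occurring in `junction`
longest_exact_match <- function(junction, d) {
  L <- nchar(d)
  for (k in L:1) {
    for (s in 1:(L - k + 1)) {
      if (grepl(substr(d, s, s + k - 1), junction, fixed = TRUE)) return(k)
    }
  }
  0L
}

#' Select one TRA and one TRB call per cell by UMI support
#'
#' Within each barcode and chain, identical (v_call, j_call, cdr3_nt) tuples
#' are grouped; the tuple supported by the most distinct UMIs wins (ties: more
#' total reads, then lexicographically smallest cdr3_nt).
#'
#' @param assignments Tibble from [assign_vdj()].
#' @return Tibble with one row per (barcode, chain): columns `barcode`,
#'   `chain`, `v_call`, `d_call`, `j_call`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`, `umis` (distinct UMI support), `reads` (total reads).
#' @export
select_cell_calls <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble(barcode = character(), chain = character(),
                  v_call = character(), d_call = character(),
                  j_call = character(), cdr3_nt = character(),
                  cdr3_aa = character(), productive = logical(),
                  umis = integer(), reads = integer()))
  }
  assignments |>
    dplyr::group_by(.data$barcode, .data$chain, .data$v_call, .data$j_call,
                    .data$cdr3_nt) |>
    dplyr::summarise(
      d_call = dplyr::first(.data$d_call),
      cdr3_aa = dplyr::first(.data$cdr3_aa),
      productive = dplyr::first(.data$productive),
      umis = dplyr::n_distinct(.data$umi),
      reads = sum(.data$n_reads),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$barcode, .data$chain) |>
    dplyr::arrange(dplyr::desc(.data$umis), dplyr::desc(.data$reads),
                   .data$cdr3_nt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("barcode", "chain", "v_call", "d_call", "j_call",
                  "cdr3_nt", "cdr3_aa", "productive", "umis", "reads")
}
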