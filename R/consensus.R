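#' Consensus-calling parameters
#'
#' The numeric knobs of the per-molecule consensus stage. Defaults are the
#' workflow's published operating point: reads within a molecule are
#' clustered at 0.9 identity; the top cluster must hold at least 50% of the
#' molecule's reads and at least twice the reads of the runner-up; a
#' consensus requires at least 3 reads; alignment columns with gap frequency
#' above 0.5 are dropped and a column whose plurality base falls below
#' support 0.5 is called `N`.
#'
#' @param identity_threshold Minimum pairwise identity to join a cluster
#'   (inclusive).
#' @param min_cluster_fraction Minimum fraction of the molecule's reads the
#'   winning cluster must hold.
#' @param dominance_ratio Required ratio of top to second cluster size.
#' @param min_reads Minimum reads per consensus.
#' @param max_error_rate Maximum tolerated per-column error rate; a column's
#'   plurality base must be supported by at least `1 - max_error_rate` of
#'   its non-gap characters, else `N` is emitted. The alternative per-read
#'   semantics (drop members whose mismatch rate to the consensus exceeds
#'   the cap, then re-call) is selected by `error_rate_scope = "read"`.
#' @param max_gap_freq Columns with a higher gap frequency are dropped.
#' @param error_rate_scope `"column"` (default) or `"read"`.
#' @return List of class `trek_consensus_params`.
#' @export
consensus_params <- function(identity_threshold = 0.9,
                             min_cluster_fraction = 0.5,
                             dominance_ratio = 2,
                             min_reads = 3,
                             max_error_rate = 0.5,
                             max_gap_freq = 0.5,
                             error_rate_scope = c("column", "read")) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            min_cluster_fraction >= 0, min_cluster_fraction <= 1,
            dominance_ratio >= 1, min_reads >= 1,
            max_error_rate >= 0, max_error_rate <= 1,
            max_gap_freq >= 0, max_gap_freq <= 1)
  structure(list(
    identity_threshold = identity_threshold,
    min_cluster_fraction = min_cluster_fraction,
    dominance_ratio = dominance_ratio,
    min_reads = as.integer(min_reads),
    max_error_rate = max_error_rate,
    max_gap_freq = max_gap_freq,
    error_rate_scope = match.arg(error_rate_scope)
  ), class = "trek_consensus_params")
}

#' Cluster the reads of one molecule at an identity threshold
#'
#' Greedy centroid clustering of the reads sharing one (barcode, UMI) key.
#' Seeds are processed in descending mean read quality (then input order); a
#' read joins the first centroid whose pairwise identity is at or above the
#' threshold, otherwise it founds a new cluster. Identity is the match count
#' of a global alignment with end-gap-free scoring divided by the longer
#' read's length, so terminal overhangs count against identity and unrelated
#' reads cannot pair up through a short chance overlap.
#'
#' @param seqs Character vector of read sequences (one molecule).
#' @param mean_quality Numeric vector of mean Phred scores, same length
#'   (used only for seed ordering; defaults to zero).
#' @param params [consensus_params()].
#' @return Integer vector of cluster ids (1 = largest cluster after
#'   relabelling by size, descending; ties by first occurrence).
#' @export
cluster_molecule_reads <- function(seqs, mean_quality = NULL,
                                   params = consensus_params()) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  if (is.null(mean_quality)) mean_quality <- rep(0, n)
  ord <- order(-mean_quality, seq_len(n))
  centroid_idx <- integer(0)
  assign <- integer(n)
  for (i in ord) {
    if (length(centroid_idx)) {
      # identical sequences join without alignment
      same <- match(seqs[i], seqs[centroid_idx])
      if (!is.na(same)) {
        assign[i] <- same
        next
      }
      ident <- pairwise_identity(seqs[i], seqs[centroid_idx])
      hit <- which(ident >= params$identity_threshold)
      if (length(hit)) {
        assign[i] <- hit[1]
        next
      }
    }
    centroid_idx <- c(centroid_idx, i)
    assign[i] <- length(centroid_idx)
  }
  # relabel so cluster 1 is the largest
  sizes <- tabulate(assign)
  relabel <- order(-sizes, seq_along(sizes))
  match(assign, relabel)
}

#' Dominance filter over a molecule's read clusters
#'
#' Keeps the top cluster iff it holds at least `min_cluster_fraction` of the
#' molecule's reads and at least `dominance_ratio` times the reads of the
#' second-largest cluster (zero when there is only one cluster).
#'
#' @param sizes Integer vector of cluster sizes, sorted descending.
#' @param params [consensus_params()].
#' @return `TRUE` if the top cluster wins, else `FALSE`.
#' @examples
#' dominance_filter(c(6, 3)) # TRUE
#' dominance_filter(c(5, 4)) # FALSE
#' @export
dominance_filter <- function(sizes, params = consensus_params()) {
  if (length(sizes) == 0) return(FALSE)
  sizes <- sort(as.numeric(sizes), decreasing = TRUE)
  second <- if (length(sizes) > 1) sizes[2] else 0
  sizes[1] / sum(sizes) >= params$min_cluster_fraction &&
    sizes[1] >= params$dominance_ratio * second
}

#' Build a consensus sequence from one read cluster
#'
#' Members are star-aligned to the longest member; alignment columns with
#' gap frequency above `max_gap_freq` are dropped; each remaining column is
#' called as the plurality base among non-gap characters, emitting `N` when
#' the plurality fraction is below `1 - max_error_rate` or when the
#' plurality is tied. Leading and trailing `N` runs are stripped. Returns
#' `NULL` when the cluster has fewer than `min_reads` members.
#'
#' @param seqs Character vector of member read sequences.
#' @param params [consensus_params()].
#' @return Consensus sequence (character scalar, possibly containing `N`),
#'   or `NULL`.
#' @export
build_consensus <- function(seqs, params = consensus_params()) {
  if (length(seqs) < params$min_reads) return(NULL)
  cols <- star_alignment_columns(seqs)
  cons <- call_columns(cols, params)
  if (params$error_rate_scope == "read" && nzchar(cons)) {
    # drop members whose per-read mismatch rate to the consensus exceeds the
    # cap, then re-call once
    keep <- vapply(seqs, function(s) {
      ident <- pairwise_identity(s, cons)
      (1 - ident) <= params$max_error_rate
    }, logical(1))
    if (!all(keep)) {
      if (sum(keep) < params$min_reads) return(NULL)
      cols <- star_alignment_columns(seqs[keep])
      cons <- call_columns(cols, params)
    }
  }
  if (!nzchar(cons)) NULL else cons
}

## star-align members to the longest member; returns a character matrix of
## alignment columns (rows = members), "-" for gaps / unaligned positions.
## Insertions relative to the centre are interleaved as extra columns.
star_alignment_columns <- function(seqs) {
  n <- length(seqs)
  centre_i <- which.max(nchar(seqs))
  centre <- seqs[centre_i]
  L <- nchar(centre)
  if (all(seqs == centre)) {
    return(matrix(rep(strsplit(centre, "")[[1]], each = n), nrow = n))
  }
  # near-identical equal-length reads align column-to-column: skip alignment
  if (all(nchar(seqs) == L)) {
    return(do.call(rbind, strsplit(seqs, "")))
  }
  others <- setdiff(seq_len(n), centre_i)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs[others]), Biostrings::DNAString(centre),
    type = "overlap", substitutionMatrix = nuc_submat(),
    gapOpening = 2, gapExtension = 1
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  sub_start <- Biostrings::start(Biostrings::subject(aln))

  # per member: centre-position characters, plus insertions keyed by
  # (preceding centre position, offset)
  base_rows <- matrix("-", nrow = n, ncol = L)
  base_rows[centre_i, ] <- strsplit(centre, "")[[1]]
  insert_map <- list() # key "pos.offset" -> named chars by member row

  for (k in seq_along(others)) {
    pc <- strsplit(pat[k], "")[[1]]
    sc <- strsplit(sub[k], "")[[1]]
    pos <- sub_start[k] - 1L # last consumed centre position
    ins_off <- 0L
    row <- others[k]
    for (t in seq_along(sc)) {
      if (sc[t] == "-") {
        ins_off <- ins_off + 1L
        key <- paste0(pos, "|", ins_off)
        ins <- insert_map[[key]] %||% character(0)
        ins[[as.character(row)]] <- pc[t]
        insert_map[[key]] <- ins
      } else {
        pos <- pos + 1L
        ins_off <- 0L
        base_rows[row, pos] <- pc[t]
      }
    }
  }
  if (!length(insert_map)) return(base_rows)
  # interleave insertion columns after their anchor centre position
  keys <- names(insert_map)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  anchor_pos <- as.integer(parts[, 1])
  anchor_off <- as.integer(parts[, 2])
  ord <- order(anchor_pos, anchor_off)
  out_cols <- vector("list", L + length(keys))
  ci <- 0L
  ki <- 1L
  for (p in 0:L) {
    if (p > 0) {
      ci <- ci + 1L
      out_cols[[ci]] <- base_rows[, p]
    }
    while (ki <= length(keys) && anchor_pos[ord[ki]] == p) {
      col <- rep("-", n)
      ins <- insert_map[[keys[ord[ki]]]]
      col[as.integer(names(ins))] <- unname(ins)
      ci <- ci + 1L
      out_cols[[ci]] <- col
      ki <- ki + 1L
    }
  }
  do.call(cbind, out_cols[seq_len(ci)])
}

## per-column plurality calling with gap-frequency and support thresholds
call_columns <- function(cols, params) {
  n <- nrow(cols)
  calls <- apply(cols, 2, function(col) {
    gap_freq <- mean(col == "-")
    if (gap_freq > params$max_gap_freq) return("")
    bases <- col[col != "-"]
    tab <- sort(table(bases), decreasing = TRUE)
    top <- tab[1]
    if (sum(tab == top) > 1) return("N") # tied plurality
    if (top / length(bases) < 1 - params$max_error_rate) return("N")
    names(tab)[1]
  })
  cons <- paste(calls, collapse = "")
  gsub("^N+|N+$", "", cons)
}

#' Call consensus molecules from corrected reads
#'
#' Groups reads by (corrected barcode, corrected UMI), clusters each group at
#' the identity threshold, applies the dominance filter and builds a
#' consensus per winning cluster.
#'
#' @param reads Tibble from [correct_reads()].
#' @param params [consensus_params()].
#' @return Tibble with one row per consensus molecule: `barcode`, `umi`,
#'   `sequence`, `n_reads` (cluster size), `fraction_of_molecule`. A
#'   `molecule_log` attribute records every molecule's outcome (`consensus`,
#'   `dominance_rejected`, `min_reads_rejected`) with its cluster sizes.
#' @export
call_consensus_molecules <- function(reads, params = consensus_params()) {
  stopifnot(all(c("corrected_barcode", "corrected_umi", "tcr_seq") %in%
                  names(reads)))
  keys <- paste(reads$corrected_barcode, reads$corrected_umi, sep = "\t")
  grp <- split(seq_len(nrow(reads)), keys)

  res <- vector("list", length(grp))
  log <- vector("list", length(grp))
  for (g in seq_along(grp)) {
    idx <- grp[[g]]
    key <- strsplit(names(grp)[g], "\t", fixed = TRUE)[[1]]
    cl <- cluster_molecule_reads(reads$tcr_seq[idx],
                                 reads$mean_quality[idx], params)
    sizes <- sort(tabulate(cl), decreasing = TRUE)
    outcome <- "consensus"
    if (!dominance_filter(sizes, params)) {
      outcome <- "dominance_rejected"
    } else {
      members <- idx[cl == 1]
      cons <- build_consensus(reads$tcr_seq[members], params)
      if (is.null(cons)) {
        outcome <- "min_reads_rejected"
      } else {
        res[[g]] <- tibble(
          barcode = key[1], umi = key[2], sequence = cons,
          n_reads = length(members),
          fraction_of_molecule = length(members) / length(idx)
        )
      }
    }
    log[[g]] <- tibble(
      barcode = key[1], umi = key[2], n_reads_total = length(idx),
      n_clusters = length(sizes),
      top_sizes = paste(head(sizes, 3), collapse = ","),
      outcome = outcome
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(barcode = character(), umi = character(),
                  sequence = character(), n_reads = integer(),
                  fraction_of_molecule = numeric())
  }
  attr(out, "molecule_log") <- dplyr::bind_rows(log)
  out
}

#' Retrieve the per-molecule outcome log
#' @param x Result of [call_consensus_molecules()].
#' @return Tibble of molecule outcomes.
#' @export
molecule_log <- function(x) attr(x, "molecule_log")
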