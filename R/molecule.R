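#' Correct cell barcodes against a whitelist
#'
#' Exact whitelist members are returned unchanged; otherwise, if exactly one
#' whitelist member lies at Hamming distance 1 (an `N` counts as a
#' mismatch), that member is returned; ambiguous (two or more neighbours) or
#' unmatched barcodes yield `NA`.
#'
#' @param barcodes Character vector of observed barcodes.
#' @param whitelist A [load_whitelist()] result or character vector.
#' @param max_mismatch Maximum mismatches to rescue (0 or 1; default 1).
#' @return Character vector of corrected barcodes, `NA` where uncorrectable.
#' @examples
#' wl <- structure(c(strrep("A", 16), strrep("G", 16)), class = "trek_whitelist")
#' correct_barcode(c(strrep("A", 16), paste0(strrep("A", 15), "C")), wl)
#' @export
correct_barcode <- function(barcodes, whitelist, max_mismatch = 1) {
  wl <- as.character(whitelist)
  stopifnot(max_mismatch %in% c(0, 1))
  out <- rep(NA_character_, length(barcodes))
  exact <- barcodes %in% wl
  out[exact] <- barcodes[exact]
  if (max_mismatch == 0 || !any(!exact)) return(out)

  wl_len <- nchar(wl[1])
  todo <- unique(barcodes[!exact])
  todo <- todo[nchar(todo) == wl_len]
  # hash lookup over all 1-substitution neighbours of each failed barcode;
  # N positions are mismatches, so substituting them is the only rescue
  wl_set <- new.env(parent = emptyenv(), size = length(wl) * 2L)
  for (b in wl) assign(b, TRUE, envir = wl_set)
  fixed <- vapply(todo, function(b) {
    hits <- character(0)
    for (p in seq_len(wl_len)) {
      orig <- substr(b, p, p)
      for (base in DNA_BASES[DNA_BASES != orig]) {
        cand <- `substr<-`(b, p, p, base)
        if (!is.null(wl_set[[cand]])) {
          hits <- c(hits, cand)
          if (length(hits) > 1) return(NA_character_)
        }
      }
    }
    if (length(hits) == 1) hits else NA_character_
  }, character(1))
  out[!exact] <- fixed[match(barcodes[!exact], todo)]
  out
}

#' Cluster UMIs within one cell barcode
#'
#' Merges UMIs that differ by a single substitution. The default method
#' takes single-linkage connected components over the Hamming-distance-1
#' graph; each component is represented by its highest-count UMI (ties
#' broken by lexicographic order). The `"directional"` alternative follows
#' the count-ratio adjacency rule used by UMI-tools: an edge a -> b requires
#' count(a) >= 2 * count(b) - 1, and components are grown from high-count
#' nodes only along such edges.
#'
#' @param umi_counts Named integer vector: UMI -> read count.
#' @param method `"components"` (default) or `"directional"`.
#' @return Named character vector mapping every input UMI to its
#'   representative UMI.
#' @examples
#' cluster_umis(c(AAAA = 5, AAAT = 1))
#' @export
cluster_umis <- function(umi_counts, method = c("components", "directional")) {
  method <- match.arg(method)
  umis <- names(umi_counts)
  stopifnot(!is.null(umis), all(umi_counts >= 1))
  n <- length(umis)
  if (n == 1) return(setNames(umis, umis))

  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    d <- hamming_vec(umis[i], umis[(i + 1):n])
    nb <- which(d == 1) + i
    for (j in nb) {
      ok <- if (method == "components") TRUE else {
        umi_counts[i] >= 2 * umi_counts[j] - 1 ||
          umi_counts[j] >= 2 * umi_counts[i] - 1
      }
      if (ok) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (s in order(-umi_counts, umis)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      if (method == "directional") {
        # only descend to strictly dominated neighbours
        nb <- adj[[v]]
        nb <- nb[umi_counts[v] >= 2 * umi_counts[nb] - 1]
      } else {
        nb <- adj[[v]]
      }
      queue <- c(queue, nb[comp[nb] == 0L])
    }
  }
  rep_of <- vapply(seq_len(cid), function(k) {
    members <- which(comp == k)
    members <- members[order(-umi_counts[members], umis[members])]
    umis[members[1]]
  }, character(1))
  setNames(rep_of[comp], umis)
}

#' Mean-quality read filter
#'
#' Discards a read iff its mean Phred score is strictly below the threshold;
#' a read whose mean is exactly the threshold is kept.
#'
#' @param quals List of integer Phred vectors (or a single vector).
#' @param threshold Minimum mean quality (default 25).
#' @return Logical vector: `TRUE` = keep.
#' @export
quality_filter <- function(quals, threshold = 25) {
  if (is.numeric(quals)) quals <- list(quals)
  vapply(quals, function(q) {
    if (length(q) == 0) abort("empty quality vector")
    mean(q) >= threshold
  }, logical(1))
}

#' Correct barcodes and UMIs and apply the quality filter
#'
#' The first three stages of the reconstruction workflow in one call:
#' barcode correction against the whitelist (1 mismatch), per-barcode UMI
#' clustering (1 mismatch), then the mean-quality filter. The filter runs
#' after correction so every discarded read is attributed to a single cause.
#'
#' @param reads Tibble from [parse_trekseq()].
#' @param whitelist A [load_whitelist()] result.
#' @param barcode_mismatch 0 or 1 (default 1).
#' @param umi_method Passed to [cluster_umis()].
#' @param min_mean_quality Mean Phred threshold (default 25).
#' @return Tibble of retained reads with added columns `corrected_barcode`,
#'   `corrected_umi` and `mean_quality`, carrying a `filter_log` attribute
#'   (tibble of `reason`/`n`: `no_whitelist_match`, `ambiguous_barcode`,
#'   `low_quality`, `short_read`, `retained`; discards plus retained sum to
#'   the parsed reads).
#' @export
correct_reads <- function(reads, whitelist, barcode_mismatch = 1,
                          umi_method = "components", min_mean_quality = 25) {
  corrected <- correct_barcode(reads$barcode, whitelist, barcode_mismatch)
  keep_bc <- !is.na(corrected)
  failed <- unique(reads$barcode[!keep_bc])
  n_ambig <- 0L
  if (length(failed)) {
    ambig <- vapply(failed, function(b) {
      count_whitelist_neighbours(b, as.character(whitelist)) >= 2
    }, logical(1))
    n_ambig <- sum(ambig[match(reads$barcode[!keep_bc], failed)])
  }
  out <- reads[keep_bc, ]
  out$corrected_barcode <- corrected[keep_bc]

  # UMI clustering within each corrected barcode
  out$corrected_umi <- out$umi
  if (nrow(out)) {
    grp <- split(seq_len(nrow(out)), out$corrected_barcode)
    for (idx in grp) {
      counts <- table(out$umi[idx])
      map <- cluster_umis(setNames(as.integer(counts), names(counts)),
                          method = umi_method)
      out$corrected_umi[idx] <- unname(map[out$umi[idx]])
    }
  }

  out$mean_quality <- vapply(out$quals, mean, numeric(1))
  keep_q <- quality_filter(out$quals, min_mean_quality)
  log <- tibble(
    reason = c("no_whitelist_match", "ambiguous_barcode", "low_quality",
               "short_read", "retained"),
    n = c(sum(!keep_bc) - n_ambig, n_ambig, sum(!keep_q),
          attr(reads, "n_dropped_short") %||% 0L, sum(keep_q))
  )
  out <- out[keep_q, ]
  attr(out, "filter_log") <- log
  out
}

## number of whitelist members within Hamming distance 1 of a barcode
count_whitelist_neighbours <- function(b, wl) {
  if (nchar(b) != nchar(wl[1])) return(0L)
  sum(hamming_vec(b, wl) <= 1)
}

#' Retrieve the filter log attached to a processed read table
#' @param x Object carrying a `filter_log` attribute.
#' @return Tibble of discard reasons and counts.
#' @export
filter_log <- function(x) attr(x, "filter_log")
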