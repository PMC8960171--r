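#' Parse a TREK-seq FASTQ pair into joined read records
#'
#' Joins Read 1 (cell barcode + UMI) with the TCR read by record order,
#' checking that ids match. The barcode is the first 16 nt of Read 1 and the
#' UMI the next 12 nt. Records whose Read 1 is shorter than 28 nt are
#' dropped and counted. `N` bases in barcode or UMI are kept here; they are
#' resolved (or the read discarded) by barcode/UMI correction downstream.
#'
#' @param r1_fastq,tcr_fastq Paths to the paired FASTQ files (gzipped or
#'   plain; auto-detected).
#' @return A tibble with columns `read_id`, `barcode`, `umi`, `tcr_seq`,
#'   `quals` (list column of integer Phred vectors), with attribute
#'   `n_dropped_short` counting records dropped for short Read 1.
#' @export
parse_trekseq <- function(r1_fastq, tcr_fastq) {
  r1 <- read_fastq_tbl(r1_fastq)
  tcr <- read_fastq_tbl(tcr_fastq)
  if (nrow(r1) != nrow(tcr)) {
    abort(sprintf("FASTQ pair record counts differ: %d vs %d",
                  nrow(r1), nrow(tcr)))
  }
  mism <- which(r1$id != tcr$id)
  if (length(mism)) {
    abort(sprintf("read id mismatch at record %d: '%s' vs '%s'",
                  mism[1], r1$id[mism[1]], tcr$id[mism[1]]))
  }
  short <- nchar(r1$seq) < R1_LEN
  out <- tibble(
    read_id = r1$id[!short],
    barcode = substr(r1$seq[!short], 1, BC_LEN),
    umi = substr(r1$seq[!short], BC_LEN + 1, R1_LEN),
    tcr_seq = tcr$seq[!short],
    quals = phred_to_int(tcr$qual[!short])
  )
  attr(out, "n_dropped_short") <- sum(short)
  out
}

## minimal FASTQ reader returning id/seq/qual character vectors
read_fastq_tbl <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path) # gzfile auto-detected by readLines via file()
  if (length(lines) %% 4 != 0) {
    abort(paste0("truncated FASTQ (line count not divisible by 4): ", path))
  }
  idx <- seq(1, length(lines), by = 4)
  ids <- lines[idx]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad)) abort(sprintf("malformed FASTQ header at record %d", bad[1]))
  tibble(id = sub("^@", "", sub("\\s.*$", "", ids)),
         seq = toupper(lines[idx + 1]),
         qual = lines[idx + 3])
}

## Phred+33 quality strings -> list of integer vectors
phred_to_int <- function(qual_strings) {
  lapply(qual_strings, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Load a cell-barcode whitelist
#'
#' @param path Plain-text file, one barcode per line.
#' @return Character vector of unique uppercase barcodes, class
#'   `trek_whitelist`.
#' @export
load_whitelist <- function(path) {
  if (!file.exists(path)) abort(paste0("whitelist not found: ", path))
  bcs <- toupper(trimws(readLines(path)))
  bcs <- bcs[nzchar(bcs)]
  if (length(bcs) == 0) abort("whitelist is empty")
  len <- unique(nchar(bcs))
  if (length(len) != 1) {
    abort(paste0("whitelist has mixed barcode lengths: ",
                 paste(len, collapse = ", ")))
  }
  if (!all(grepl("^[ACGT]+$", bcs))) abort("whitelist barcodes must be ACGT")
  structure(unique(bcs), class = "trek_whitelist")
}

#' Write per-cell chain calls as an AIRR Rearrangement table
#'
#' One row per chain per cell, with the AIRR standard column names
#' (`cell_id`, `locus`, `v_call`, `d_call`, `j_call`, `junction`,
#' `junction_aa`, `productive`, `duplicate_count`, `umi_count`).
#'
#' @param cells Tibble of selected per-cell chain calls, as returned by
#'   [select_cell_calls()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_airr <- function(cells, path) {
  airr <- tibble(
    cell_id = cells$barcode %||% character(0),
    locus = cells$chain %||% character(0),
    v_call = cells$v_call %||% character(0),
    d_call = cells$d_call %||% NA_character_,
    j_call = cells$j_call %||% character(0),
    junction = cells$cdr3_nt %||% character(0),
    junction_aa = cells$cdr3_aa %||% NA_character_,
    productive = cells$productive %||% logical(0),
    duplicate_count = cells$reads %||% integer(0),
    umi_count = cells$umis %||% integer(0)
  )
  readr::write_tsv(airr, path)
  invisible(path)
}

#' Read an AIRR Rearrangement table written by [write_airr()]
#'
#' @param path TSV path.
#' @return Tibble in the package's per-cell chain-call layout (`barcode`,
#'   `chain`, `v_call`, `d_call`, `j_call`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`, `reads`, `umis`).
#' @export
read_airr <- function(path) {
  airr <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            cell_id = "c", locus = "c", v_call = "c",
                            d_call = "c", j_call = "c", junction = "c",
                            junction_aa = "c", productive = "l",
                            duplicate_count = "i", umi_count = "i"))
  tibble(
    barcode = airr$cell_id, chain = airr$locus, v_call = airr$v_call,
    d_call = airr$d_call, j_call = airr$j_call, cdr3_nt = airr$junction,
    cdr3_aa = airr$junction_aa, productive = airr$productive,
    reads = airr$duplicate_count, umis = airr$umi_count
  )
}
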