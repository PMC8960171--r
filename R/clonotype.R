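#' Call TRB clonotypes and compute normalized clone sizes
#'
#' Cells are grouped into clonotypes by their selected TRB call. The
#' clonotype key is the (TRB `v_call`, `cdr3_nt`) pair by default; the
#' nucleotide junction is the stricter reading of "the same TCR", and
#' amino-acid grouping or inclusion of the J call are available through
#' `key`. The normalized size of a clonotype is its cell count divided by
#' the number of cells in which any TCR (TRA or TRB) was detected in the
#' sample, so normalized sizes sum to at most 1 (exactly 1 when every
#' TCR-bearing cell has a TRB call).
#'
#' @param cell_calls Tibble from [select_cell_calls()] (one sample).
#' @param sample_id Sample label recorded on each clonotype.
#' @param key Character vector of columns forming the clonotype key
#'   (default `c("v_call", "cdr3_nt")`; may include `"j_call"` or use
#'   `"cdr3_aa"`).
#' @return Tibble of class `trek_clonotypes`: `sample_id`, `clonotype_id`,
#'   key columns, `size`, `normalized_size`, `member_barcodes` (list
#'   column). Attribute `n_tcr_cells` holds the denominator.
#' @export
call_clonotypes <- function(cell_calls, sample_id = "sample1",
                            key = c("v_call", "cdr3_nt")) {
  stopifnot(all(key %in% names(cell_calls)))
  n_tcr_cells <- dplyr::n_distinct(cell_calls$barcode)
  trb <- cell_calls[cell_calls$chain == "TRB", , drop = FALSE]
  if (nrow(trb) == 0 || n_tcr_cells == 0) {
    out <- tibble(sample_id = character(), clonotype_id = character(),
                  size = integer(), normalized_size = numeric(),
                  member_barcodes = list())
    attr(out, "n_tcr_cells") <- n_tcr_cells
    class(out) <- c("trek_clonotypes", class(out))
    return(out)
  }
  out <- trb |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(size = dplyr::n_distinct(.data$barcode),
                     member_barcodes = list(sort(unique(.data$barcode))),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size),
                   dplyr::across(dplyr::all_of(key))) |>
    dplyr::mutate(sample_id = sample_id,
                  clonotype_id = sprintf("%s_CT%04d", sample_id,
                                         dplyr::row_number()),
                  normalized_size = .data$size / n_tcr_cells) |>
    dplyr::select("sample_id", "clonotype_id", dplyr::all_of(key),
                  "size", "normalized_size", "member_barcodes")
  attr(out, "n_tcr_cells") <- n_tcr_cells
  class(out) <- c("trek_clonotypes", class(out))
  out
}

#' Rank clonotypes by normalized size
#'
#' @param clonotypes A `trek_clonotypes` tibble.
#' @return Tibble `rank`, `clonotype_id`, `normalized_size`, descending by
#'   normalized size with ties broken by clonotype id (stable).
#' @export
rank_distribution <- function(clonotypes) {
  if (nrow(clonotypes) == 0) abort("no clonotypes to rank")
  clonotypes |>
    as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$normalized_size), .data$clonotype_id) |>
    dplyr::transmute(rank = dplyr::row_number(), .data$clonotype_id,
                     .data$normalized_size)
}

#' Summarise chain detection per cell type
#'
#' Classifies every TCR-bearing cell as `TRA only`, `TRB only` or `both`,
#' and tabulates the three mutually exclusive classes per cell-type label.
#' Barcodes absent from the annotation are reported under cell type
#' `"unannotated"`.
#'
#' @param cell_calls Tibble from [select_cell_calls()].
#' @param annotation Tibble with columns `barcode`, `cell_type` (and
#'   optionally `sample_id`, `group`).
#' @return Tibble `cell_type`, `detection` (`TRA only`/`TRB only`/`both`),
#'   `n`, `proportion` (within cell type; sums to 1 per type).
#' @export
chain_detection_summary <- function(cell_calls, annotation) {
  per_cell <- cell_calls |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      detection = dplyr::case_when(
        all(c("TRA", "TRB") %in% .data$chain) ~ "both",
        "TRB" %in% .data$chain ~ "TRB only",
        TRUE ~ "TRA only"
      ),
      .groups = "drop"
    ) |>
    dplyr::left_join(annotation[, intersect(c("barcode", "cell_type"),
                                            names(annotation))],
                     by = "barcode") |>
    dplyr::mutate(cell_type = dplyr::coalesce(.data$cell_type, "unannotated"))
  per_cell |>
    dplyr::count(.data$cell_type, .data$detection, name = "n") |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Fraction of TCR-bearing cells per cell type
#'
#' @inheritParams chain_detection_summary
#' @return Tibble `cell_type`, `n`, `fraction`; fractions sum to 1 over all
#'   TCR-bearing cells.
#' @export
tcr_celltype_composition <- function(cell_calls, annotation) {
  cells <- unique(cell_calls$barcode)
  ann <- annotation[, intersect(c("barcode", "cell_type"), names(annotation))]
  tibble(barcode = cells) |>
    dplyr::left_join(ann, by = "barcode") |>
    dplyr::mutate(cell_type = dplyr::coalesce(.data$cell_type, "unannotated")) |>
    dplyr::count(.data$cell_type, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
}
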