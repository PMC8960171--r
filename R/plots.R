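#' Clonotype rank-abundance plot
#'
#' Normalized clone size against clonotype rank (log10 y), the standard
#' display for spotting clonally expanded samples against a flat,
#' polyclonal background.
#'
#' @param clonotypes A `trek_clonotypes` tibble (or several samples bound
#'   together; colour = `sample_id`).
#' @return A ggplot object.
#' @export
plot_rank_abundance <- function(clonotypes) {
  df <- as_tibble(clonotypes) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$normalized_size), .data$clonotype_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$normalized_size,
                                   colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clonotype rank", y = "normalized clone size",
                  colour = "sample") +
    ggplot2::theme_bw()
}

#' Autoplot method for clonotype tables (rank-abundance curve)
#' @param object A `trek_clonotypes` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot trek_clonotypes
autoplot.trek_clonotypes <- function(object, ...) plot_rank_abundance(object)

#' Chain-detection stacked bars per cell type
#'
#' @param chain_summary Output of [chain_detection_summary()].
#' @return A ggplot object.
#' @export
plot_chain_detection <- function(chain_summary) {
  ggplot2::ggplot(chain_summary,
                  ggplot2::aes(x = .data$cell_type, y = .data$proportion,
                               fill = .data$detection)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of TCR-bearing cells",
                  fill = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Box plots of a score across clone-size bins
#'
#' @param data Per-cell tibble with `clone_size` and `score` columns (as
#'   joined by [run_analytics()]).
#' @param breaks Bin upper edges, as in [clone_size_bins()].
#' @return A ggplot object.
#' @export
plot_clone_size_bins <- function(data, breaks = c(1, 5, 20, Inf)) {
  labels <- bin_labels(breaks)
  df <- dplyr::mutate(data, bin = cut(.data$clone_size, c(0, breaks),
                                      labels = labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "TCR clone size (cells)", y = "signature score") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
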