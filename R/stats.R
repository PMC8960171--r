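#' Exact two-sample rank-sum test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test. For combined sample
#' sizes up to `exact_max` with no ties the null distribution of the
#' rank sum is enumerated exactly over all `choose(n_x + n_y, n_x)` rank
#' assignments and the two-sided p-value is twice the smaller tail
#' probability, capped at 1. With ties or larger samples a normal
#' approximation with tie correction is used (no continuity correction).
#'
#' At complete separation of groups of sizes 5 and 4 the exact two-sided
#' p-value is 2/126 = 0.0159.
#'
#' @param x,y Numeric vectors (no NA/NaN).
#' @param exact_max Largest combined size for exact enumeration (default 12).
#' @return One-row tibble: `statistic` (rank sum W of `x`), `p_value`,
#'   `n_x`, `n_y`, `method` (`"exact"` or `"normal"`).
#' @examples
#' exact_ranksum(1:5, 6:9)$p_value # 2/126
#' @export
exact_ranksum <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) abort("empty input vector")
  if (anyNA(x) || anyNA(y)) abort("NA/NaN not allowed")
  n_x <- length(x); n_y <- length(y); n <- n_x + n_y
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n_x)])
  has_ties <- anyDuplicated(c(x, y)) > 0

  if (!has_ties && n <= exact_max) {
    sums <- colSums(matrix(seq_len(n)[combn(n, n_x)], nrow = n_x))
    lo <- mean(sums <= w)
    hi <- mean(sums >= w)
    p <- min(1, 2 * min(lo, hi))
    return(tibble(statistic = w, p_value = p, n_x = n_x, n_y = n_y,
                  method = "exact"))
  }
  mu <- n_x * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n_x * n_y / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(tibble(statistic = w, p_value = 1, n_x = n_x, n_y = n_y,
                  method = "normal"))
  }
  z <- (w - mu) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  tibble(statistic = w, p_value = p, n_x = n_x, n_y = n_y, method = "normal")
}

#' Spearman correlation between clone size and a per-cell score
#'
#' Spearman rank correlation with average ranks for ties; the p-value uses
#' the t approximation. Zero variance in either variable leaves `rho`
#' undefined (`NA`) with `degenerate = TRUE`.
#'
#' @param data Tibble with the two variables.
#' @param size_col,score_col Column names (defaults `normalized_size`,
#'   `score`).
#' @return One-row tibble: `rho`, `p_value`, `n`, `degenerate`.
#' @export
clone_exhaustion_correlation <- function(data, size_col = "normalized_size",
                                         score_col = "score") {
  x <- data[[size_col]]; y <- data[[score_col]]
  if (length(x) < 3) abort("need at least 3 cells")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = length(x),
                  degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         degenerate = FALSE)
}

#' Kruskal-Wallis rank sum test over groups
#'
#' Tie-corrected H statistic with a chi-squared p-value on k - 1 degrees of
#' freedom (wraps `stats::kruskal.test`). When every value is identical the
#' statistic is 0 and the p-value 1 by convention, with `degenerate = TRUE`.
#'
#' @param groups List of numeric vectors (at least 2 nonempty).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0)) {
    abort("all groups must be nonempty")
  }
  vals <- unlist(groups)
  if (length(unique(vals)) == 1) {
    return(tibble(statistic = 0, df = length(groups) - 1L, p_value = 1,
                  degenerate = TRUE))
  }
  kt <- stats::kruskal.test(groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, degenerate = FALSE)
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction; errors when a row or column marginal is
#' zero (expected counts must be positive).
#'
#' @param counts Matrix (e.g. cell type x donor group).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
celltype_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero marginal in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Summarise a score by clone-size bin
#'
#' Bins cells by the cell count of their clonotype (default bins 1, 2-5,
#' 6-20, >20) and reports per-bin occupancy and score quartiles, together
#' with the mean normalized clone size per bin (the parenthetical values of
#' the box-plot display convention).
#'
#' @param data Tibble with one row per cell: columns `clone_size` (cells in
#'   the cell's clonotype), `score`, and optionally `normalized_size`.
#' @param breaks Upper edges of the bins (default `c(1, 5, 20, Inf)`).
#' @return Tibble: `bin`, `n`, `median`, `q1`, `q3`,
#'   `mean_normalized_size` (NA when `normalized_size` is absent).
#' @export
clone_size_bins <- function(data, breaks = c(1, 5, 20, Inf)) {
  stopifnot(all(c("clone_size", "score") %in% names(data)))
  labels <- bin_labels(breaks)
  data |>
    dplyr::mutate(bin = cut(.data$clone_size, c(0, breaks), labels = labels)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = if (dplyr::n()) median(.data$score) else NA_real_,
      q1 = if (dplyr::n()) unname(quantile(.data$score, 0.25)) else NA_real_,
      q3 = if (dplyr::n()) unname(quantile(.data$score, 0.75)) else NA_real_,
      mean_normalized_size = if ("normalized_size" %in% names(data) &&
                                 dplyr::n()) {
        mean(.data$normalized_size)
      } else NA_real_,
      .groups = "drop"
    )
}

bin_labels <- function(breaks) {
  lo <- c(1, head(breaks, -1) + 1)
  hi <- breaks
  ifelse(is.infinite(hi), paste0(">", lo - 1),
         ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi)))
}
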