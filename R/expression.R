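#' Simulate a gene-by-cell count matrix with a signature effect
#'
#' Draws negative-binomial counts for a toy gene universe (including a block
#' of mitochondrial `MT-` genes so QC is exercised) and shifts the signature
#' genes of a designated cell group upward. The effect is additive on the
#' log2 mean: signature genes in the designated group have their
#' negative-binomial mean multiplied by `2^effect`, so `effect = 0` is
#' exactly the null and `effect = log2(5)` a five-fold shift.
#'
#' @param barcodes Character vector of cell barcodes.
#' @param cell_groups Character vector, same length: group label per cell.
#' @param signature Character vector of signature gene names (must be a
#'   subset of the simulated universe).
#' @param effect Log2 shift applied to signature genes in `effect_group`
#'   (NaN is an error; negative values allowed).
#' @param effect_group Group label receiving the shift.
#' @param n_genes Size of the gene universe (default 300; gene names
#'   `GENE001` ... plus 10 `MT-` genes).
#' @param base_mu,dispersion Negative-binomial mean and size parameters.
#' @param seed Integer seed; required.
#' @param out_dir If non-`NULL`, writes `matrix.mtx`, `genes.txt`,
#'   `barcodes.txt` and `annotation.csv` there.
#' @return List with `counts` (a `dgCMatrix`, genes x cells) and
#'   `annotation` (tibble `barcode`, `sample_id`, `cell_type`, `group`).
#' @export
simulate_expression <- function(barcodes, cell_groups, signature,
                                effect = 0, effect_group = NULL,
                                n_genes = 300, base_mu = 5, dispersion = 2,
                                seed = NULL, out_dir = NULL) {
  if (is.null(seed)) abort("`seed` is required in simulate_expression()")
  if (is.nan(effect)) abort("`effect` must not be NaN")
  stopifnot(length(barcodes) == length(cell_groups), n_genes > 20)
  genes <- c(sprintf("GENE%03d", seq_len(n_genes - 10)),
             sprintf("MT-SIM%d", 1:10))
  missing <- setdiff(signature, genes)
  if (length(missing)) {
    abort(paste0("signature genes outside the simulated universe: ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(effect_group)) effect_group <- sort(unique(cell_groups))[1]

  withr::with_seed(seed, {
    n_c <- length(barcodes)
    # per-gene baseline means on a log-normal-ish grid for realistic spread
    gene_mu <- base_mu * exp(stats::rnorm(length(genes), 0, 0.6))
    names(gene_mu) <- genes
    mu <- matrix(rep(gene_mu, n_c), nrow = length(genes))
    shift_cols <- which(cell_groups == effect_group)
    sig_rows <- match(signature, genes)
    if (length(shift_cols) && length(sig_rows) && effect != 0) {
      mu[sig_rows, shift_cols] <- mu[sig_rows, shift_cols] * 2^effect
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = dispersion),
                     nrow = length(genes),
                     dimnames = list(genes, barcodes))
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    annotation <- tibble(barcode = barcodes, sample_id = "sim",
                         cell_type = "T-cell", group = cell_groups)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_count_matrix(counts, out_dir)
      readr::write_csv(annotation, file.path(out_dir, "annotation.csv"))
    }
    list(counts = counts, annotation = annotation)
  })
}

#' Write a gene-by-cell count matrix as MTX plus name files
#' @param counts Sparse matrix (genes x cells) with dimnames.
#' @param dir Output directory (`matrix.mtx`, `genes.txt`, `barcodes.txt`).
#' @return The directory, invisibly.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.txt"))
  writeLines(colnames(counts), file.path(dir, "barcodes.txt"))
  invisible(dir)
}

#' Read a gene-by-cell count matrix written by [write_count_matrix()]
#' @param dir Directory containing `matrix.mtx`, `genes.txt`, `barcodes.txt`.
#' @return A `dgCMatrix` with gene rownames and barcode colnames.
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.txt"))
  colnames(m) <- readLines(file.path(dir, "barcodes.txt"))
  if (anyDuplicated(rownames(m))) abort("duplicate gene names in matrix")
  m
}

#' Read gene sets from a GMT file
#' @param path GMT path (tab-separated: name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line (need name, desc, genes)")
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Cell quality-control filter
#'
#' Retains cells with at least `min_umis` total counts, at least `min_genes`
#' detected genes, and a mitochondrial fraction strictly below `max_mito`.
#'
#' @param counts Sparse or dense gene-by-cell count matrix with gene names.
#' @param min_umis,min_genes Inclusive lower bounds.
#' @param max_mito Exclusive upper bound on the mitochondrial read fraction.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes; if
#'   no gene matches, a warning is raised and the fraction is 0.
#' @return List with `counts` (filtered matrix) and `log` (tibble `barcode`,
#'   `total_umis`, `n_genes`, `mito_fraction`, `keep`).
#' @export
qc_filter <- function(counts, min_umis = 1000, min_genes = 500,
                      max_mito = 0.30, mito_prefix = "MT-") {
  total <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito_rows <- startsWith(rownames(counts), mito_prefix)
  if (!any(mito_rows)) {
    warn(paste0("no genes match mito_prefix '", mito_prefix,
                "'; mitochondrial fraction set to 0"))
    mito_frac <- rep(0, ncol(counts))
  } else {
    mito_frac <- unname(Matrix::colSums(counts[mito_rows, , drop = FALSE]) /
                          pmax(total, 1))
  }
  keep <- total >= min_umis & ngene >= min_genes & mito_frac < max_mito
  list(
    counts = counts[, keep, drop = FALSE],
    log = tibble(barcode = colnames(counts), total_umis = as.numeric(total),
                 n_genes = as.integer(ngene), mito_fraction = mito_frac,
                 keep = keep)
  )
}

#' Score cells for a gene signature (module score)
#'
#' Computes a per-cell module score in the style of Seurat's
#' `AddModuleScore`: counts are log-normalised (counts per 10k, `log1p`),
#' all genes are binned into `n_bins` equal-occupancy bins by their average
#' normalised expression, and for each signature gene `n_ctrl` control genes
#' are sampled (with replacement) from the gene's bin. The score is the mean
#' normalised expression of the signature genes minus the mean of the
#' pooled control genes, per cell.
#'
#' @param counts Gene-by-cell count matrix.
#' @param genes Character vector of signature genes (at least one must be
#'   present in the matrix; missing genes are dropped with a warning).
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes sampled per signature gene (default 100).
#' @param seed Integer seed for the control draw; required.
#' @param signature_name Label recorded in the output.
#' @return Tibble `barcode`, `signature`, `score`.
#' @export
score_signature <- function(counts, genes, n_bins = 24, n_ctrl = 100,
                            seed = NULL, signature_name = "signature") {
  if (is.null(seed)) abort("`seed` is required in score_signature()")
  present <- intersect(genes, rownames(counts))
  if (length(present) == 0) {
    abort(paste0("no signature genes found in matrix; missing: ",
                 paste(genes, collapse = ", ")))
  }
  if (length(present) < length(genes)) {
    warn(paste0("signature genes absent from matrix: ",
                paste(setdiff(genes, present), collapse = ", ")))
  }
  norm <- lognorm_cp10k(counts)
  avg <- Matrix::rowMeans(norm)
  n_bins_eff <- min(n_bins, length(avg))
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins_eff)
  names(bin) <- rownames(norm)

  withr::with_seed(seed, {
    ctrl <- unlist(lapply(present, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
    sig_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
    ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
    tibble(barcode = colnames(counts), signature = signature_name,
           score = as.numeric(sig_mean - ctrl_mean))
  })
}

## log-normalise: counts per 10k per cell, then log1p
lognorm_cp10k <- function(counts) {
  sf <- Matrix::colSums(counts)
  sf[sf == 0] <- 1
  norm <- counts %*% Matrix::Diagonal(x = 1e4 / sf)
  colnames(norm) <- colnames(counts)
  log1p(norm)
}
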