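#' Build a run configuration
#'
#' A nested list of every tunable in the workflow, serialisable to/from
#' YAML. Unknown sections or keys are rejected so a typo cannot silently
#' fall back to a default.
#'
#' @param ... Named overrides, either whole sections (lists) or `section.key`
#'   scalars, e.g. `run_config(seed = 3, consensus = list(min_reads = 4))`.
#' @return List of class `trek_run_config`.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) {
      abort(paste0("unknown config section or key: ", nm))
    }
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      bad <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad)) {
        abort(paste0("unknown key(s) in section '", nm, "': ",
                     paste(bad, collapse = ", ")))
      }
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "trek_run_config")
}

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "trekr_run",
    paths = list(
      r1_fastq = NULL, tcr_fastq = NULL, whitelist = NULL,
      reference_fasta = NULL, reference_anchors = NULL,
      annotation_csv = NULL, counts_dir = NULL, gmt = NULL
    ),
    sim = list(
      n_v = 4L, n_j = 3L, chains = c("TRA", "TRB"),
      n_cells = 100L, clone_size_weights = c("1" = 0.5, "10" = 0.5),
      reads_per_molecule = 5L, umis_per_chain = 3L,
      per_base_error_rate = 0.005, indel_rate = 0,
      barcode_error_rate = 0.02, umi_error_rate = 0, swap_rate = 0.01,
      tra_prob = 0.75, quality_high = 37L, quality_low = 11L, n_decoys = 50L
    ),
    molecule = list(barcode_mismatch = 1L, umi_method = "components",
                    min_mean_quality = 25),
    consensus = list(identity_threshold = 0.9, min_cluster_fraction = 0.5,
                     dominance_ratio = 2, min_reads = 3L,
                     max_error_rate = 0.5, max_gap_freq = 0.5,
                     error_rate_scope = "column"),
    vdj = list(match = 1, mismatch = -1, gap_opening = 2, gap_extension = 1,
               min_score = 15, d_min_exact = 5L),
    clonotype = list(key = c("v_call", "cdr3_nt"), sample_id = "sample1"),
    expression = list(min_umis = 1000, min_genes = 500, max_mito = 0.30,
                      mito_prefix = "MT-", n_bins = 24L, n_ctrl = 100L,
                      apply_qc = TRUE)
  )
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return For `read_run_config()`, a `trek_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim$clone_size_weights)) {
    raw$sim$clone_size_weights <- unlist(raw$sim$clone_size_weights)
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg A `trek_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  raw <- unclass(cfg)
  # yaml drops names on atomic vectors; keep the size -> weight map as a map
  raw$sim$clone_size_weights <- as.list(raw$sim$clone_size_weights)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Simulate a full input set under a run configuration
#'
#' Builds the toy reference, simulates the repertoire and reads, and writes
#' everything under `out_dir/sim/`. The configuration's `paths` are filled
#' in so the reconstruction step can run directly on the result.
#'
#' @param cfg A [run_config()].
#' @return The updated configuration, with attributes `truth` (the
#'   repertoire ground truth) and `sim_paths`.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "trek_run_config"))
  sim_dir <- file.path(cfg$out_dir, "sim")
  dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
  s <- cfg$sim
  ref <- build_toy_reference(s$n_v, s$n_j, chains = s$chains, seed = cfg$seed)
  write_segment_reference(ref, file.path(sim_dir, "segments.fasta"),
                          file.path(sim_dir, "segments_anchors.tsv"))
  scfg <- sim_config(
    n_cells = s$n_cells, clone_size_weights = s$clone_size_weights,
    reads_per_molecule = s$reads_per_molecule,
    umis_per_chain = s$umis_per_chain,
    per_base_error_rate = s$per_base_error_rate, indel_rate = s$indel_rate,
    barcode_error_rate = s$barcode_error_rate,
    umi_error_rate = s$umi_error_rate, swap_rate = s$swap_rate,
    tra_prob = s$tra_prob, quality_high = s$quality_high,
    quality_low = s$quality_low, n_decoys = s$n_decoys, seed = cfg$seed
  )
  truth <- simulate_repertoire(ref, scfg)
  paths <- simulate_reads(truth, ref, scfg, file.path(sim_dir, "trek"))
  ann <- truth$cells[, c("barcode", "sample_id", "cell_type")]
  ann_path <- file.path(sim_dir, "annotation.csv")
  readr::write_csv(ann, ann_path)
  cfg$paths$r1_fastq <- paths$r1
  cfg$paths$tcr_fastq <- paths$tcr
  cfg$paths$whitelist <- paths$whitelist
  cfg$paths$reference_fasta <- file.path(sim_dir, "segments.fasta")
  cfg$paths$reference_anchors <- file.path(sim_dir, "segments_anchors.tsv")
  cfg$paths$annotation_csv <- ann_path
  attr(cfg, "truth") <- truth
  attr(cfg, "sim_paths") <- paths
  cfg
}

#' Run the reconstruction workflow
#'
#' parse -> barcode/UMI correction + quality filter -> per-molecule
#' clustering, dominance filter and consensus -> V(D)J assignment ->
#' per-cell chain selection -> clonotype calling. Writes the AIRR
#' Rearrangement table, the clonotype table, the filter and molecule logs
#' and a JSON run manifest (config hash, input checksums, per-stage record
#' counts) under `out_dir/reconstruct/`.
#'
#' @param cfg A [run_config()] whose `paths` point at the inputs.
#' @return List of class `trek_run`: `cell_calls`, `clonotypes`,
#'   `assignments`, `consensus`, `filter_log`, `molecule_log`, `manifest`,
#'   `dir`.
#' @export
run_reconstruct <- function(cfg) {
  stopifnot(inherits(cfg, "trek_run_config"))
  p <- cfg$paths
  for (key in c("r1_fastq", "tcr_fastq", "whitelist", "reference_fasta",
                "reference_anchors")) {
    if (is.null(p[[key]]) || !file.exists(p[[key]])) {
      abort(paste0("input missing for reconstruct: ", key, " = ",
                   p[[key]] %||% "<unset>"))
    }
  }
  out <- file.path(cfg$out_dir, "reconstruct")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  reads <- parse_trekseq(p$r1_fastq, p$tcr_fastq)
  wl <- load_whitelist(p$whitelist)
  corrected <- correct_reads(reads, wl,
                             barcode_mismatch = cfg$molecule$barcode_mismatch,
                             umi_method = cfg$molecule$umi_method,
                             min_mean_quality = cfg$molecule$min_mean_quality)
  cons_params <- do.call(consensus_params, cfg$consensus)
  consensus <- call_consensus_molecules(corrected, cons_params)
  ref <- load_segment_reference(p$reference_fasta, p$reference_anchors)
  assignments <- assign_vdj(consensus, ref, do.call(vdj_params, cfg$vdj))
  cell_calls <- select_cell_calls(assignments)
  clonotypes <- call_clonotypes(cell_calls,
                                sample_id = cfg$clonotype$sample_id,
                                key = cfg$clonotype$key)

  write_airr(cell_calls, file.path(out, "airr.tsv"))
  readr::write_tsv(as_tibble(clonotypes) |>
                     dplyr::select(-"member_barcodes"),
                   file.path(out, "clonotypes.tsv"))
  readr::write_tsv(filter_log(corrected), file.path(out, "filter_log.tsv"))
  readr::write_tsv(molecule_log(consensus), file.path(out, "molecule_log.tsv"))

  manifest <- list(
    config_hash = config_hash(cfg),
    inputs = as.list(tools::md5sum(unlist(p[!vapply(p, is.null, logical(1))]))),
    stages = list(
      parsed_reads = nrow(reads),
      dropped_short = attr(reads, "n_dropped_short"),
      retained_reads = nrow(corrected),
      molecules = nrow(molecule_log(consensus)),
      consensus_molecules = nrow(consensus),
      assigned_molecules = nrow(assignments),
      cells_with_tcr = dplyr::n_distinct(cell_calls$barcode),
      clonotypes = nrow(clonotypes)
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(cell_calls = cell_calls, clonotypes = clonotypes,
                 assignments = assignments, consensus = consensus,
                 filter_log = filter_log(corrected),
                 molecule_log = molecule_log(consensus),
                 manifest = manifest, dir = out),
            class = "trek_run")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the repertoire and signature analytics
#'
#' Derives every figure-ready summary from the reconstruction outputs (the
#' AIRR and clonotype tables on disk) plus the cell annotation and,
#' optionally, a count matrix and gene sets: clonotype rank distribution,
#' chain-detection summary and TCR cell-type composition, per-signature
#' module scores with a clone-size/score correlation and clone-size-bin
#' summaries. All tables are written as TSV under `out_dir/analytics/`.
#'
#' @param cfg A [run_config()]; `paths$annotation_csv` is required,
#'   `paths$counts_dir` and `paths$gmt` optional.
#' @return List of class `trek_analytics` with the computed tables.
#' @export
run_analytics <- function(cfg) {
  stopifnot(inherits(cfg, "trek_run_config"))
  rec_dir <- file.path(cfg$out_dir, "reconstruct")
  airr_path <- file.path(rec_dir, "airr.tsv")
  if (!file.exists(airr_path)) {
    abort(paste0("reconstruction output not found: ", airr_path))
  }
  if (is.null(cfg$paths$annotation_csv) ||
      !file.exists(cfg$paths$annotation_csv)) {
    abort("annotation_csv is required for analytics")
  }
  ann <- readr::read_csv(cfg$paths$annotation_csv, show_col_types = FALSE)
  req <- c("barcode", "cell_type")
  if (!all(req %in% names(ann))) {
    abort(paste0("annotation must contain columns: ",
                 paste(req, collapse = ", ")))
  }
  cell_calls <- read_airr(airr_path)
  clonotypes <- call_clonotypes(cell_calls,
                                sample_id = cfg$clonotype$sample_id,
                                key = cfg$clonotype$key)
  out <- file.path(cfg$out_dir, "analytics")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  res <- list(
    rank_distribution = rank_distribution(clonotypes),
    chain_detection = chain_detection_summary(cell_calls, ann),
    composition = tcr_celltype_composition(cell_calls, ann)
  )

  if (!is.null(cfg$paths$counts_dir) && !is.null(cfg$paths$gmt)) {
    counts <- read_count_matrix(cfg$paths$counts_dir)
    if (isTRUE(cfg$expression$apply_qc)) {
      qc <- qc_filter(counts, min_umis = cfg$expression$min_umis,
                      min_genes = cfg$expression$min_genes,
                      max_mito = cfg$expression$max_mito,
                      mito_prefix = cfg$expression$mito_prefix)
      counts <- qc$counts
      res$qc_log <- qc$log
    }
    sets <- read_gmt(cfg$paths$gmt)
    scores <- purrr::imap_dfr(sets, function(genes, nm) {
      score_signature(counts, genes, n_bins = cfg$expression$n_bins,
                      n_ctrl = cfg$expression$n_ctrl, seed = cfg$seed,
                      signature_name = nm)
    })
    res$scores <- scores
    # per-cell clone size / score join (TRB clonotype membership)
    member <- as_tibble(clonotypes) |>
      dplyr::select("clonotype_id", "size", "normalized_size",
                    "member_barcodes") |>
      tidyr::unnest_longer("member_barcodes", values_to = "barcode")
    cell_sizes <- member |>
      dplyr::rename(clone_size = "size")
    joined <- dplyr::inner_join(scores, cell_sizes, by = "barcode")
    if (nrow(joined) >= 3) {
      res$correlation <- joined |>
        dplyr::group_by(.data$signature) |>
        dplyr::group_modify(~ clone_exhaustion_correlation(
          .x, size_col = "normalized_size", score_col = "score")) |>
        dplyr::ungroup()
      res$bins <- joined |>
        dplyr::group_by(.data$signature) |>
        dplyr::group_modify(~ clone_size_bins(.x)) |>
        dplyr::ungroup()
    }
  }
  for (nm in names(res)) {
    readr::write_tsv(res[[nm]], file.path(out, paste0(nm, ".tsv")))
  }
  res$dir <- out
  structure(res, class = "trek_analytics")
}

#' Run simulate + reconstruct + analytics in one call
#' @param cfg A [run_config()].
#' @return List with elements `cfg`, `reconstruct`, `analytics`.
#' @export
run_all <- function(cfg) {
  cfg <- run_simulate(cfg)
  rec <- run_reconstruct(cfg)
  ana <- run_analytics(cfg)
  list(cfg = cfg, reconstruct = rec, analytics = ana)
}

#' Print a reconstruction run summary
#' @param x A `trek_run`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
#' @method print trek_run
print.trek_run <- function(x, ...) {
  s <- x$manifest$stages
  cat("<trek_run>", "\n",
      "  reads parsed/retained: ", s$parsed_reads, "/", s$retained_reads, "\n",
      "  molecules -> consensus -> assigned: ", s$molecules, " -> ",
      s$consensus_molecules, " -> ", s$assigned_molecules, "\n",
      "  cells with TCR: ", s$cells_with_tcr,
      "; clonotypes: ", s$clonotypes, "\n", sep = "")
  invisible(x)
}

#' Glance at a reconstruction run
#' @param x A `trek_run`.
#' @param ... Unused.
#' @return One-row tibble of stage counts.
#' @export
glance.trek_run <- function(x, ...) {
  as_tibble(x$manifest$stages)
}

#' Tidy a reconstruction run into per-cell chain calls
#' @param x A `trek_run`.
#' @param ... Unused.
#' @return Tibble of per-cell chain calls.
#' @export
tidy.trek_run <- function(x, ...) x$cell_calls

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
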