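Package: trekr
Title: Reconstruction of T-Cell Receptor Clonotypes from 3' Single-Cell
    RNA-seq Enrichment Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs T-cell receptor (TCR) clonotypes from targeted
    enrichment reads carried on 3' single-cell RNA-seq libraries.  Implements
    the full desk-scale workflow: cell-barcode correction against a chemistry
    whitelist, UMI clustering, read-quality filtering, per-molecule sequence
    clustering with a dominance filter, consensus calling, V(D)J segment
    assignment with CDR3 junction extraction, per-cell chain selection by UMI
    support, TRB clonotype calling with normalized clone sizes, and the
    downstream repertoire and exhaustion-signature analytics (module scoring,
    exact rank-sum, Kruskal-Wallis, Spearman and chi-squared comparisons).
    A synthetic-data module generates clonally structured repertoires, paired
    FASTQ files with quality-scored errors, barcode swaps, whitelists and
    signature-structured expression matrices with full ground truth, so every
    stage is testable without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
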