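# trekr

Reconstruction of T-cell receptor (TCR) clonotypes from 3' single-cell
RNA-seq enrichment reads, with the downstream repertoire and
exhaustion-signature analytics.

## What problem this solves

Droplet 3' scRNA-seq libraries never reach the TCR variable region, which
sits at the 5' end of the *TRA*/*TRB* transcripts. Targeted enrichment
protocols sequence that region in a companion library while keeping the
droplet cell barcode, so each TCR read can be linked back to a cell with a
full transcriptome. `trekr` is the computational half of that design: it
takes the paired FASTQs (Read 1 = 16 nt cell barcode + 12 nt UMI; TCR read
= up to 150 nt of rearranged sequence), a barcode whitelist and a V/J
segment reference, and produces per-cell chain calls (AIRR Rearrangement
format), TRB clonotypes with normalized sizes, and figure-ready summaries
linking clonal expansion to cell types and gene-signature scores.

It is aimed at immunogenomics analysts who want a transparent,
fully-testable desk-scale implementation of the workflow — every stage is
an ordinary R function over tibbles — plus a simulator that generates
clonally structured repertoires with complete ground truth, so the whole
pipeline can be validated offline.

## The method in brief

1. **Barcode correction** against the whitelist, allowing one mismatch;
   ambiguous barcodes are discarded. **UMI clustering** merges UMIs at
   Hamming distance 1 (connected components; a directional variant is
   available). Reads with mean Phred < 25 are removed.
2. **Consensus calling** per (barcode, UMI) molecule: greedy clustering at
   0.9 identity, a dominance filter (top cluster ≥ 50% of reads and ≥ 2×
   the runner-up, guarding against barcode swapping), then a ≥ 3-read
   plurality consensus with per-column support ≥ 0.5 and gap frequency
   ≤ 0.5.
3. **V(D)J assignment**: local alignment (match +1, mismatch −1, gap open
   −2, extend −1) against every V and J; the CDR3 junction spans the codon
   aligned to the V's conserved Cys through the codon aligned to the J's
   conserved Phe/Trp. Per cell and chain, the (V, J, CDR3) tuple with the
   most distinct UMIs wins.
4. **Clonotypes** are TRB-only, keyed by (V gene, CDR3 nucleotide); the
   normalized clone size is cells in the clonotype over all
   TCR-detected cells, so sizes within a sample sum to 1.
5. **Analytics**: rank-abundance curves, chain detection and cell-type
   composition of TCR-bearing cells, module (signature) scores with
   expression-matched controls, exact Wilcoxon rank-sum, Kruskal-Wallis,
   Spearman and chi-squared comparisons, and clone-size-bin summaries.

The methods vignette (`vignettes/trekr-methods.Rmd`) documents every
parameter, default and design decision.

## Worked example

Simulate a 60-cell repertoire (half singletons, half 10-cell clones) and
reconstruct it:

```r
library(trekr)

cfg <- run_config(seed = 42, out_dir = file.path(tempdir(), "demo"),
                  sim = list(n_cells = 60,
                             clone_size_weights = c("1" = 0.5, "10" = 0.5)))
cfg <- run_simulate(cfg)   # writes FASTQs, whitelist, reference, truth
rec <- run_reconstruct(cfg)
rec
#> <trek_run>
#>   reads parsed/retained: 1545/1545
#>   molecules -> consensus -> assigned: 319 -> 309 -> 309
#>   cells with TCR: 60; clonotypes: 15
```

1,545 reads collapse to 319 candidate molecules; 309 survive the dominance
filter and the ≥ 3-read requirement (the ~10 rejected ones are
barcode-swap chimeras the filter exists to catch), and all 60 cells get a
TCR call grouping into 15 clonotypes — 5 clones of 10 cells plus 10
singletons, exactly the simulated structure:

```r
tibble::as_tibble(rec$clonotypes)[1:2, c("clonotype_id", "v_call", "cdr3_nt",
                                         "size", "normalized_size")]
#>   clonotype_id   v_call cdr3_nt            size normalized_size
#> 1 sample1_CT0001 TRBV1  TGTGATATTCATCTGG     10           0.167
#> 2 sample1_CT0002 TRBV2  TGCGCATTC            10           0.167
```

Each 10-cell clone holds 10/60 ≈ 0.167 of the TCR-detected repertoire.
`run_analytics(cfg)` adds rank-abundance tables, chain-detection and
cell-type summaries (and, given a count matrix and GMT gene sets,
per-cell signature scores, clone-size bins and the clone-size/score
correlation); `plot_rank_abundance()`, `plot_chain_detection()` and
`plot_clone_size_bins()` draw them.

Comparing five control against four affected sample-level scores at
complete separation reproduces the familiar exact rank-sum p-value:

```r
exact_ranksum(c(0.41, 0.12, 0.25, 0.30, 0.22), c(0.55, 0.61, 0.48, 0.70))
#>   statistic p_value   n_x   n_y method
#> 1        15  0.0159     5     4 exact
```

0.0159 is 2/126 — the smallest two-sided p attainable at those sample
sizes.

## Command line

A thin CLI over the same functions lives at `inst/exec/trekr`
(`simulate`, `reconstruct`, `analyze`, `all` subcommands):

```sh
Rscript inst/exec/trekr all --config run.yaml --out-dir my_run
```
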