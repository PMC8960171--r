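# Independent oracles used to cross-check package computations.

# brute-force barcode correction: full Hamming scan over the whitelist
brute_correct_barcode <- function(bc, wl) {
  d <- vapply(wl, function(w) {
    sum(utf8ToInt(w) != utf8ToInt(bc))
  }, integer(1), USE.NAMES = FALSE)
  if (any(d == 0)) return(bc)
  hit <- which(d == 1)
  if (length(hit) == 1) wl[hit] else NA_character_
}

# brute-force UMI single-linkage components via igraph on the full
# pairwise distance matrix
brute_umi_components <- function(umi_counts) {
  umis <- names(umi_counts)
  n <- length(umis)
  d <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    sum(utf8ToInt(umis[i]) != utf8ToInt(umis[j]))
  }))
  g <- igraph::graph_from_adjacency_matrix(d == 1, mode = "undirected")
  comp <- igraph::components(g)$membership
  rep_of <- vapply(seq_len(max(comp)), function(k) {
    members <- which(comp == k)
    members <- members[order(-umi_counts[members], umis[members])]
    umis[members[1]]
  }, character(1))
  setNames(rep_of[comp], umis)
}

naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# tie-corrected Kruskal-Wallis H from the textbook rank formula
naive_kruskal_h <- function(groups) {
  vals <- unlist(groups)
  n <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(vals)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

naive_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
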