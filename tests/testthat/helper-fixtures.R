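# fixtures and independent oracles used across test files

counts_tbl <- function(bait, control, uniq,
                       acc = sprintf("P%03d", seq_along(bait))) {
  tibble::tibble(accession = acc, bait_spc = as.integer(bait),
                 control_spc = as.integer(control),
                 unique_peptides = as.integer(uniq))
}

meta_tbl <- function(acc, length_aa = 500, localization = "nuclear",
                     abundance_ppm = 10) {
  tibble::tibble(accession = acc,
                 gene_symbol = paste0("g", acc),
                 length_aa = as.integer(rep_len(length_aa, length(acc))),
                 localization = rep_len(localization, length(acc)),
                 abundance_ppm = rep_len(abundance_ppm, length(acc)))
}

# TMT abundance table realizing prescribed per-replicate mutant/control
# ratios, control channels fixed at `base`
tmt_from_ratios <- function(r1, r2, base = 100,
                            acc = sprintf("P%03d", seq_along(r1))) {
  tibble::tibble(accession = acc,
                 ctl_1 = rep_len(base, length(r1)),
                 ctl_2 = rep_len(base, length(r1)),
                 mut_1 = base * r1, mut_2 = base * r2)
}

# brute-force NSAF: direct transcription of the formula, independent of
# compute_nsaf()'s implementation
nsaf_oracle <- function(counts, meta) {
  rows <- counts[counts$bait_spc > 0, ]
  saf <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    L <- meta$length_aa[meta$accession == rows$accession[i]]
    saf[i] <- rows$bait_spc[i] / L
  }
  setNames(saf / sum(saf), rows$accession)
}

# row-by-row predicate evaluation of the candidate filter
filter_oracle <- function(counts, min_spectra = 10, min_fold = 4,
                          min_uniq = 2) {
  keep <- character(0)
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    ok <- row$unique_peptides >= min_uniq && row$bait_spc >= min_spectra &&
      (row$control_spc == 0 || row$bait_spc / row$control_spc >= min_fold)
    if (ok) keep <- c(keep, row$accession)
  }
  sort(keep)
}

# exhaustive hypergeometric upper tail: explicit combinatorial summation
# over the support, usable for N <= 60
hyper_tail_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# induced-subgraph oracle: nodes and edges by direct set logic
induced_subgraph_oracle <- function(query, edges, min_score) {
  vocab <- unique(c(edges$protein_a, edges$protein_b))
  nodes <- sort(intersect(query, vocab))
  kept <- edges[edges$combined_score > min_score &
                  edges$protein_a %in% nodes & edges$protein_b %in% nodes, ]
  list(nodes = nodes,
       edges = kept[order(kept$protein_a, kept$protein_b), ])
}
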