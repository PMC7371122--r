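# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different algorithms from the package code paths.

# per-protein scan: a protein is an anchor iff each required domain has a
# hit at or below the threshold
bf_anchors <- function(hits, required, threshold) {
  keys <- unique(paste(hits$genome_id, hits$protein_id, sep = "\r"))
  ok <- vapply(keys, function(k) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1]]
    sub <- hits[hits$genome_id == p[1] & hits$protein_id == p[2], , drop = FALSE]
    all(vapply(required, function(d)
      any(sub$domain_acc == d & sub$e_value <= threshold), logical(1)))
  }, logical(1))
  sort(keys[ok])
}

# window enumeration: all index windows [i, j] of a start-sorted contig
# whose genes share one strand and whose consecutive gaps pass; the cluster
# of an anchor is the unique maximal valid window containing it
bf_extract <- function(feats, anchor_idx, max_gap) {
  n <- nrow(feats)
  link_ok <- rep(TRUE, max(n - 1, 0))
  if (n > 1) for (i in seq_len(n - 1)) {
    gap <- max(0, feats$start[i + 1] - feats$end[i] - 1)
    link_ok[i] <- identical(feats$strand[i + 1], feats$strand[i]) &&
      !is.na(feats$strand[i]) && gap <= max_gap
  }
  best <- c(anchor_idx, anchor_idx)
  for (i in seq_len(anchor_idx)) for (j in anchor_idx:n) {
    links <- if (j > i) link_ok[i:(j - 1)] else logical(0)
    if (all(links) && (j - i) > (best[2] - best[1])) best <- c(i, j)
  }
  best[1]:best[2]
}

# union-find connected components over cluster ids
bf_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges$id_a[k]); rb <- find(edges$id_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

# random start-sorted contig with mixed strands and gaps straddling the
# 400 bp rule, for extraction-oracle comparisons
random_contig_features <- function(n_genes, max_gap = 400) {
  start <- integer(n_genes); end <- integer(n_genes)
  pos <- sample(100:500, 1)
  for (i in seq_len(n_genes)) {
    len <- sample(200:1200, 1)
    start[i] <- pos; end[i] <- pos + len - 1
    pos <- end[i] + 1 + sample(c(sample(0:max_gap, 1),
                                 sample((max_gap + 1):(3 * max_gap), 1)), 1)
  }
  data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)), contig_id = "c1",
             start = start, end = end,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             protein_id = sprintf("p%03d", seq_len(n_genes)),
             domains = "", stringsAsFactors = FALSE)
}

# random tree with positive branch lengths for NJ/midpoint properties
random_pos_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr
}

# canonical partition of a clustering for set comparison
partition_of <- function(groups) {
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[[`, character(1), 1))])
}

# map recovered clusters to planted truth rows by genome + ordered members
cluster_truth_key <- function(genome_id, gene_ids) paste(genome_id, gene_ids)
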