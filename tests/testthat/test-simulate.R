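test_that("planted clusters follow the stated copy law and geometry", {
  sim <- generate_genomes(
    n_genomes = 5,
    taxa = list(list(taxon = "T", copy_law = copy_law("constant", value = 2))),
    cluster_size_range = c(4L, 4L), seed = 1)
  tr <- sim$truth
  expect_equal(nrow(tr$planted_clusters), 10L)      # 5 genomes x always 2
  expect_true(all(lengths(lapply(tr$planted_clusters$gene_ids, function(x)
    strsplit(x, ",")[[1]])) == 4L))
  # every planted anchor appears in exactly one planted cluster
  all_anchor <- unname(unlist(tr$planted_anchors))
  expect_equal(sort(all_anchor), sort(tr$planted_clusters$anchor_gene_id))

  # zero-copy law gives genomes with no anchors and empty truth
  sim0 <- generate_genomes(
    n_genomes = 3, decoy_rate = 0,
    taxa = list(list(taxon = "T", copy_law = copy_law("constant", value = 0))),
    seed = 2)
  expect_equal(nrow(sim0$truth$planted_clusters), 0L)
  expect_length(sim0$truth$planted_anchors, 0L)
})

test_that("identical seeds give byte-identical annotations", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- generate_genomes(n_genomes = 4, seed = 77)
    for (g in sim$genomes)
      write_genome_annotation(g, file.path(d, paste0(g$genome_id, ".gff3")))
  }
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("planted clusters are maximal under the extraction ruler", {
  sim <- generate_genomes(n_genomes = 8, seed = 13)
  params <- mgc_params()
  for (g in sim$genomes) {
    tr <- sim$truth$planted_clusters
    tr <- tr[tr$genome_id == g$genome_id, , drop = FALSE]
    f <- g$features
    for (i in seq_len(nrow(tr))) {
      cf <- f[f$contig_id == tr$contig_id[i], , drop = FALSE]
      genes <- strsplit(tr$gene_ids[i], ",")[[1]]
      idx <- match(genes, cf$gene_id)
      # internal gaps below threshold, one strand
      expect_true(all(diff(idx) == 1L))
      expect_true(all(cf$strand[idx] == tr$strand[i]))
      if (length(idx) > 1) {
        gaps <- cf$start[idx[-1]] - cf$end[idx[-length(idx)]] - 1L
        expect_true(all(gaps < params$max_intergenic_gap))
      }
      # flanks violate: preceding/following gene too far or absent
      lo <- min(idx); hi <- max(idx)
      if (lo > 1) {
        gap <- cf$start[lo] - cf$end[lo - 1] - 1L
        expect_true(gap > params$max_intergenic_gap ||
                      cf$strand[lo - 1] != tr$strand[i])
      }
      if (hi < nrow(cf)) {
        gap <- cf$start[hi + 1] - cf$end[hi] - 1L
        expect_true(gap > params$max_intergenic_gap ||
                      cf$strand[hi + 1] != tr$strand[i])
      }
    }
  }
})

test_that("infeasible geometry under a fixed contig length is an error", {
  expect_error(
    generate_genomes(n_genomes = 2, contig_length = 5000, decoy_rate = 20,
                     taxa = list(list(taxon = "T",
                                      copy_law = copy_law("constant", value = 3))),
                     seed = 4),
    "exceeds contig_length")
})

test_that("with zero noise the dual-domain genes are exactly the planted anchors", {
  sim <- generate_genomes(n_genomes = 6, seed = 21)
  hits <- generate_domain_hits(sim$genomes, sim$truth, seed = 22)
  req <- sim$truth$required_domains
  both <- tapply(hits$domain_acc[hits$domain_acc %in% req],
                 hits$protein_id[hits$domain_acc %in% req],
                 function(d) length(unique(d)))
  dual <- sort(names(both)[both == 2])
  planted_prot <- sort(unique(
    sim$truth$gene_domains$protein_id[
      sim$truth$gene_domains$gene_id %in% unlist(sim$truth$planted_anchors)]))
  expect_equal(dual, planted_prot)
})

test_that("single-domain decoys appear at the stated rate and never become anchors", {
  sim <- generate_genomes(
    n_genomes = 5, decoy_rate = 20,
    taxa = list(list(taxon = "T", copy_law = copy_law("constant", value = 0))),
    seed = 31)
  n_decoys <- sum(vapply(sim$genomes, function(g) nrow(g$features), integer(1)))
  hits <- generate_domain_hits(sim$genomes, sim$truth,
                               single_domain_rate = 0.5, seed = 32)
  req <- mgc_params()$required_domains
  one_dom <- hits[hits$domain_acc %in% req, , drop = FALSE]
  # binomial count: within 4 sd of n/2
  expect_gt(nrow(one_dom), n_decoys / 2 - 4 * sqrt(n_decoys * 0.25))
  expect_lt(nrow(one_dom), n_decoys / 2 + 4 * sqrt(n_decoys * 0.25))
  anchors <- find_anchors(hits)
  expect_equal(nrow(anchors$anchors), 0L)
})

test_that("an E-value law above the threshold yields no anchors downstream", {
  sim <- generate_genomes(n_genomes = 4, seed = 41)
  hits <- generate_domain_hits(sim$genomes, sim$truth,
                               e_law = function(n) rep(1e-3, n), seed = 42)
  expect_gt(nrow(hits), 0L)
  expect_equal(nrow(find_anchors(hits)$anchors), 0L)
})

test_that("sequence sets hit their planted identity targets", {
  ss <- generate_sequence_set(30, n_families = 2, within_identity = 0.95,
                              between_identity = 0.5, length = 300, seed = 7)
  expect_equal(length(ss$sequences), 30L)
  fams <- split(ss$truth$seq_id, ss$truth$family)
  ids_within <- c()
  for (members in fams) {
    pairs <- utils::combn(members, 2)
    ids_within <- c(ids_within, apply(pairs, 2, function(p)
      pairwise_identity(as.character(ss$sequences[[p[1]]]),
                        as.character(ss$sequences[[p[2]]]))))
  }
  expect_lt(abs(mean(ids_within) - 0.95), 0.03)
  cross <- sapply(fams[[1]][1:5], function(a) sapply(fams[[2]][1:5], function(b)
    pairwise_identity(as.character(ss$sequences[[a]]),
                      as.character(ss$sequences[[b]]))))
  expect_lt(abs(mean(cross) - 0.5), 0.08)

  # degenerate settings
  ss1 <- generate_sequence_set(6, 2, 1.0, 0.4, length = 50, seed = 3)
  for (members in split(ss1$truth$seq_id, ss1$truth$family))
    expect_length(unique(as.character(ss1$sequences[members])), 1L)
  ss2 <- generate_sequence_set(5, 1, 0.9, 0.0, length = 50, seed = 3)
  expect_length(unique(ss2$truth$family), 1L)
  expect_error(generate_sequence_set(10, 2, 0.9, 0.01, length = 50, seed = 1),
               "unreachable")
})

test_that("additive distance matrices match hand-computed path sums", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:4);")
  d <- generate_additive_distances(tr)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 6)
  expect_equal(d["B", "C"], 7)
  d2 <- generate_additive_distances(ape::read.tree(text = "(A:1,B:1);"))
  expect_equal(d2["A", "B"], 2)
  for (seed in 1:5) {
    set.seed(seed)
    tr <- random_pos_tree(7)
    d <- generate_additive_distances(tr)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
  tr0 <- ape::read.tree(text = "(A:0,B:1);")
  expect_error(generate_additive_distances(tr0), "positive branch lengths")
})
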