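mk_genome <- function(start, end, strand, contig = "c1", genome_id = "G1",
                      domains = "") {
  n <- length(start)
  genome_annotation(genome_id, data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), contig_id = contig,
    start = start, end = end, strand = strand,
    protein_id = sprintf("p%02d", seq_len(n)), domains = domains,
    stringsAsFactors = FALSE))
}

test_that("extension follows the gap and strand rules on the worked locus", {
  g <- mk_genome(c(100, 600, 1400), c(500, 900, 1800), c("+", "+", "+"))
  cl <- extract_cluster(g, "g02")           # gaps: 99 (in), 499 (out)
  expect_equal(strsplit(cl$member_ids, ",")[[1]], c("g01", "g02"))
  expect_equal(c(cl$start, cl$end), c(100L, 900L))

  # anchor alone on a contig
  g1 <- mk_genome(100, 500, "+")
  cl1 <- extract_cluster(g1, "g01")
  expect_equal(cl1$member_ids, "g01")
  expect_equal(cl1$n_members, 1L)

  # adjacent opposite-strand gene is excluded at any distance
  g2 <- mk_genome(c(100, 520), c(500, 900), c("+", "-"))
  expect_equal(extract_cluster(g2, "g01")$member_ids, "g01")

  # overlapping genes count as gap 0
  g3 <- mk_genome(c(100, 450), c(500, 900), c("+", "+"))
  expect_equal(extract_cluster(g3, "g01")$n_members, 2L)

  # missing strand terminates extension
  g4 <- mk_genome(c(100, 600, 1100), c(500, 900, 1500), c("+", NA, "+"))
  expect_equal(extract_cluster(g4, "g01")$member_ids, "g01")
  expect_error(extract_cluster(g4, "g02"), "no strand")

  expect_error(extract_cluster(g, "nope"), "unknown anchor")
})

test_that("returned clusters are maximal and idempotent", {
  for (seed in 1:10) {
    set.seed(seed)
    f <- random_contig_features(20)
    g <- genome_annotation("G1", f)
    anchor <- sample(g$features$gene_id, 1)
    cl <- extract_cluster(g, anchor)
    members <- strsplit(cl$member_ids, ",")[[1]]
    idx <- match(members, g$features$gene_id)
    # maximality: flanking gene violates strand or gap
    p <- mgc_params()
    if (min(idx) > 1) {
      i <- min(idx)
      gap <- max(0, g$features$start[i] - g$features$end[i - 1] - 1)
      expect_true(g$features$strand[i - 1] != cl$strand ||
                    gap > p$max_intergenic_gap)
    }
    if (max(idx) < nrow(g$features)) {
      i <- max(idx)
      gap <- max(0, g$features$start[i + 1] - g$features$end[i] - 1)
      expect_true(g$features$strand[i + 1] != cl$strand ||
                    gap > p$max_intergenic_gap)
    }
    # idempotence: extracting from the member list returns the same cluster
    sub <- genome_annotation("G1", g$features[idx, , drop = FALSE])
    cl2 <- extract_cluster(sub, anchor)
    expect_equal(cl2$member_ids, cl$member_ids)
    expect_equal(c(cl2$start, cl2$end), c(cl$start, cl$end))
  }
})

test_that("extraction equals brute-force window enumeration on random contigs", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:50, 1)
    f <- random_contig_features(n)
    g <- genome_annotation("G1", f)
    anchor_idx <- sample(n, 1)
    anchor <- g$features$gene_id[anchor_idx]
    cl <- extract_cluster(g, anchor)
    oracle <- g$features$gene_id[bf_extract(g$features, anchor_idx, 400)]
    expect_equal(strsplit(cl$member_ids, ",")[[1]], oracle, label = paste("seed", seed))
  }
})

test_that("anchors sharing one run merge into a single cluster", {
  g <- mk_genome(c(100, 600, 1000), c(500, 950, 1400), c("+", "+", "+"),
                 domains = c("PF00724,PF07992", "PF00128", "PF00724,PF07992"))
  anchors <- structure(list(
    anchors = data.frame(genome_id = "G1", protein_id = c("p01", "p03"),
                         stringsAsFactors = FALSE),
    params = mgc_params()), class = "anchor_set")
  cl <- extract_all(list(g), anchors)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$anchor_ids, "g01,g03")
  expect_equal(cl$domain_string, "PF00724,PF07992,PF00128,PF00724,PF07992")

  # anchors on different contigs stay distinct
  f2 <- rbind(g$features,
              within(g$features[1, ], { gene_id <- "g04"; protein_id <- "p04"
                                        contig_id <- "c2" }))
  g2 <- genome_annotation("G1", f2)
  anchors2 <- structure(list(
    anchors = data.frame(genome_id = "G1", protein_id = c("p01", "p04"),
                         stringsAsFactors = FALSE),
    params = mgc_params()), class = "anchor_set")
  cl2 <- extract_all(list(g2), anchors2)
  expect_equal(nrow(cl2), 2L)
  expect_setequal(cl2$contig_id, c("c1", "c2"))

  expect_error(extract_all(list(g), structure(list(
    anchors = data.frame(genome_id = "GX", protein_id = "p01"),
    params = mgc_params()), class = "anchor_set")), "unknown genome")
})

test_that("noiseless planted clusters are recovered gene-for-gene", {
  sim <- generate_genomes(n_genomes = 10, seed = 19)
  hits <- generate_domain_hits(sim$genomes, sim$truth, seed = 20)
  anchors <- find_anchors(hits)
  genomes <- attach_domains(sim$genomes, hits)
  cl <- extract_all(genomes, anchors)
  expect_equal(sort(cluster_truth_key(cl$genome_id, cl$member_ids)),
               sort(cluster_truth_key(sim$truth$planted_clusters$genome_id,
                                      sim$truth$planted_clusters$gene_ids)))
})

test_that("deduplication collapses only identical ordered keys", {
  cl <- data.frame(
    cluster_id = c("c1", "c2", "c3", "c4"),
    genome_id = "G", contig_id = "x", strand = "+",
    start = 1L, end = 2L, n_members = c(3L, 3L, 3L, 2L),
    anchor_ids = "a", member_ids = "m",
    domain_string = c("P1,P2,P3", "P1,P2,P3", "P3,P2,P1", "P1,P2,P3"),
    stringsAsFactors = FALSE)
  dd <- deduplicate_clusters(cl, key = "domain_string")
  expect_equal(dd$clusters$cluster_id, c("c1", "c3"))
  expect_equal(dd$redundancy$representative_id[dd$redundancy$cluster_id == "c2"], "c1")
  # same multiset, different order: NOT collapsed
  expect_true("c3" %in% dd$clusters$cluster_id)
  # gene-count key separates c4 from c1
  dd2 <- deduplicate_clusters(cl, key = "gene_count_domain_string")
  expect_setequal(dd2$clusters$cluster_id, c("c1", "c3", "c4"))
  dd0 <- deduplicate_clusters(cl[0, ])
  expect_equal(nrow(dd0$clusters), 0L)
})
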