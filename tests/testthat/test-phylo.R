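test_that("pairwise identity matches hand alignments and is symmetric", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_error(pairwise_identity("", "AAAA"), "non-empty")
  set.seed(2)
  aa <- Biostrings::AA_STANDARD
  for (i in 1:5) {
    a <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 35, replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  # terminal gaps are excluded from the denominator
  expect_equal(pairwise_identity("CCCC", "MCCCC"), 1.0)
})

test_that("greedy clustering honours the identity guarantee and planted truth", {
  seqs <- c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA", s3 = "AAAAAAAAAA")
  out <- greedy_identity_cluster(seqs, 0.9)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_members, 3L)

  ss <- generate_sequence_set(20, n_families = 2, within_identity = 0.95,
                              between_identity = 0.5, length = 200, seed = 7)
  cl <- greedy_identity_cluster(ss$sequences, 0.9)
  got <- partition_of(lapply(cl$member_ids, function(x) strsplit(x, ",")[[1]]))
  want <- partition_of(split(ss$truth$seq_id, ss$truth$family))
  expect_equal(got, want)
  # every member is within threshold of its centroid
  for (i in seq_len(nrow(cl))) {
    cen <- as.character(ss$sequences[[cl$centroid_id[i]]])
    for (m in strsplit(cl$member_ids[i], ",")[[1]])
      expect_gte(pairwise_identity(as.character(ss$sequences[[m]]), cen), 0.9)
  }
  expect_error(greedy_identity_cluster(unname(as.character(ss$sequences))),
               "unique names")
})

test_that("representative selection keeps small clusters whole and is seeded", {
  cl <- data.frame(cluster_id = c("SC1", "SC2", "SC3"),
                   centroid_id = c("a", "d", "z"),
                   member_ids = c("a,b,c", "d,e,f,g,h,i,j,k", "z"),
                   n_members = c(3L, 8L, 1L), representative_ids = "",
                   stringsAsFactors = FALSE)
  r1 <- select_representatives(cl, k = 5, seed = 42)
  expect_equal(r1$representative_ids[1], "a,b,c")        # size <= k: all kept
  expect_equal(r1$representative_ids[3], "z")            # singleton kept
  expect_length(strsplit(r1$representative_ids[2], ",")[[1]], 5L)
  r2 <- select_representatives(cl, k = 5, seed = 42)
  expect_identical(r1, r2)                               # reproducible
  r3 <- select_representatives(cl, k = 5, seed = 43)
  expect_true(all(strsplit(r3$representative_ids[2], ",")[[1]] %in%
                    strsplit(cl$member_ids[2], ",")[[1]]))
})

test_that("alignment trimming removes only high-gap columns", {
  aln <- Biostrings::AAStringSet(c(a = "MK-A", b = "MK-A", c = "M-CA", d = "MKCA"))
  tr <- trim_alignment(aln, 0.5)
  # column 3 has 2/4 gaps (kept at 0.5); make one with 3/4
  aln2 <- Biostrings::AAStringSet(c(a = "MK-A", b = "MK-A", c = "M--A", d = "MKCA"))
  tr2 <- trim_alignment(aln2, 0.5)
  expect_equal(Biostrings::width(tr2)[1], 3L)
  expect_equal(attr(tr2, "kept_columns"), c(1L, 2L, 4L))
  expect_equal(as.character(tr2[["c"]]), "M-A")
  # gap-free input unchanged; max_gap_fraction 1 is the identity
  aln3 <- Biostrings::AAStringSet(c(a = "MKCA", b = "MKCA"))
  expect_equal(as.character(trim_alignment(aln3, 0.5)), as.character(aln3))
  expect_equal(as.character(trim_alignment(aln2, 1.0)), as.character(aln2))
  expect_error(trim_alignment(Biostrings::AAStringSet(c(a = "MK", b = "MKC"))),
               "ragged")
})

test_that("alignment concatenation matches widths and gap-fills", {
  a1 <- Biostrings::AAStringSet(c(x = strrep("A", 40), y = strrep("C", 40)))
  a2 <- Biostrings::AAStringSet(c(x = strrep("D", 60), y = strrep("E", 60)))
  m <- concatenate_alignments(a1, a2)
  expect_equal(unique(Biostrings::width(m)), 100L)
  expect_equal(as.character(m[["x"]]), paste0(strrep("A", 40), strrep("D", 60)))
  # id present in only one block: gap fill with warning
  a3 <- Biostrings::AAStringSet(c(x = "MK", y = "MR", z = "MW"))
  a4 <- Biostrings::AAStringSet(c(x = "AC", y = "AD"))
  expect_warning(m2 <- concatenate_alignments(a3, a4), "gap-filled")
  expect_equal(as.character(m2[["z"]]), "MW--")
  expect_error(concatenate_alignments(
    Biostrings::AAStringSet(c(q = "MK")), a4), "share no sequence ids")
})

test_that("alignment distances count mismatches over shared ungapped columns", {
  aln <- Biostrings::AAStringSet(c(a = "MKCA", b = "MKCA", c = "MKCT", d = "M-CT"))
  d <- alignment_distances(aln)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.25)
  expect_equal(d["a", "d"], 1 / 3)          # gapped column excluded
  expect_equal(d, t(d))
  dp <- alignment_distances(aln, correction = "poisson")
  expect_equal(dp["a", "c"], -log(0.75))
})

test_that("neighbor joining recovers additive trees exactly", {
  d <- generate_additive_distances(ape::read.tree(text = "((A:1,B:2):1,C:4);"))
  tr <- nj_tree(d)
  d2 <- ape::cophenetic.phylo(tr)
  expect_equal(d2[rownames(d), colnames(d)], d, tolerance = 1e-12)
  # two taxa: one edge split evenly
  tr2 <- nj_tree(matrix(c(0, 5, 5, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sort(tr2$edge.length), c(2.5, 2.5))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  for (seed in 1:20) {
    set.seed(seed)
    src <- random_pos_tree(sample(4:8, 1))
    d <- generate_additive_distances(src)
    tr <- nj_tree(d)
    d2 <- ape::cophenetic.phylo(tr)
    expect_lt(max(abs(d2[rownames(d), colnames(d)] - d)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(src), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
  # independent library cross-check on one matrix
  set.seed(99)
  src <- random_pos_tree(7)
  d <- generate_additive_distances(src)
  ref <- ape::nj(d)
  expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(nj_tree(d))), 0,
               ignore_attr = TRUE)
})

test_that("midpoint rooting balances the longest leaf-to-leaf path", {
  mr <- midpoint_root(ape::read.tree(text = "((A:1,B:3):1,C:6);"))
  depth <- ape::node.depth.edgelength(mr)[seq_along(mr$tip.label)]
  names(depth) <- mr$tip.label
  expect_equal(unname(depth["B"]), 5.0)
  expect_equal(unname(depth["C"]), 5.0)
  # balanced quartet roots at the central edge midpoint
  q <- midpoint_root(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  dq <- ape::node.depth.edgelength(q)[1:4]
  expect_true(all(abs(dq - dq[1]) < 1e-9))
  expect_error(midpoint_root(ape::read.tree(text = "(A:0,B:0);")), "midpoint undefined")
  # leaf relabelling permutes but does not change depths
  tr <- ape::read.tree(text = "((A:1,B:3):1,C:6);")
  tr2 <- tr; tr2$tip.label <- c("C", "A", "B")[match(tr$tip.label, c("A", "B", "C"))]
  d1 <- sort(ape::node.depth.edgelength(midpoint_root(tr))[1:3])
  d2 <- sort(ape::node.depth.edgelength(midpoint_root(tr2))[1:3])
  expect_equal(d1, d2)
})

test_that("outgroup rooting splits the separating branch", {
  q <- ape::read.tree(text = "((A:1,B:1):1,(C:1,O:1):1);")
  r <- outgroup_root(q, "O")
  root <- length(r$tip.label) + 1L
  kids <- r$edge[r$edge[, 1] == root, 2]
  expect_true(any(kids == which(r$tip.label == "O")))
  # outgroup cherry: root on the subtending edge, split at its midpoint
  t2 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):2,(O1:1,O2:1):2);")
  r2 <- outgroup_root(ape::unroot(t2), c("O1", "O2"))
  expect_true(ape::is.monophyletic(r2, c("O1", "O2")))
  root2 <- length(r2$tip.label) + 1L
  e2 <- r2$edge.length[r2$edge[, 1] == root2]
  expect_equal(e2[1], e2[2])
  # non-monophyletic outgroup errors naming the leaves
  t3 <- ape::unroot(ape::read.tree(text = "((A:1,O1:1):1,(O2:1,B:1):1);"))
  expect_error(outgroup_root(t3, c("O1", "O2")), "O1, O2")
  expect_error(outgroup_root(q, "nope"), "not in tree")
})

test_that("N50 follows the cumulative-half definition and is order invariant", {
  expect_equal(n50(c(100, 60, 40, 20)), 60)
  expect_equal(n50(c(20, 40, 100, 60)), 60)      # order invariant
  expect_equal(n50(rep(7, 5)), 7)                # equal contigs
  expect_error(n50(numeric(0)), "empty")
  expect_error(n50(c(10, -5)), "positive")
  out <- n50_filter(list(g1 = c(50000), g2 = c(100, 60, 40, 20),
                         g3 = c(60000, 45000)), threshold = 50000)
  expect_true(out$pass[out$genome_id == "g1"])   # inclusive boundary
  expect_false(out$pass[out$genome_id == "g2"])
  expect_equal(out$n50[out$genome_id == "g3"], 60000)
})
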