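#' Global-alignment pairwise identity
#'
#' Identity between two protein sequences under Needleman-Wunsch global
#' alignment with a flat scoring scheme (documented defaults: match +1,
#' mismatch -1, gap opening 6, gap extension 1). The identity denominator
#' is the number of alignment columns between the first and last column at
#' which both sequences are aligned — i.e. terminal gap columns are
#' excluded, internal gaps count as non-identical columns.
#'
#' @param a,b Sequences (character strings or `AAString`).
#' @param match,mismatch,gap_opening,gap_extension Alignment scores.
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_opening = 6, gap_extension = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  letters_seen <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]],
                           Biostrings::AA_STANDARD))
  sm <- matrix(mismatch, length(letters_seen), length(letters_seen),
               dimnames = list(letters_seen, letters_seen))
  diag(sm) <- match
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sm,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- which(pa != "-" & pb != "-")
  if (!length(both)) return(0)
  cols <- min(both):max(both)
  sum(pa[cols] == pb[cols] & pa[cols] != "-") / length(cols)
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are scanned in the stated order (default: decreasing length,
#' ties by input order). Each sequence joins the first existing cluster
#' whose founding centroid it matches at `min_identity` or above, otherwise
#' it founds a new cluster. Deterministic for a fixed order; every member
#' is guaranteed to have identity at least `min_identity` to its centroid.
#'
#' @param sequences Named character vector or `AAStringSet` with unique ids.
#' @param min_identity Identity threshold in `[0, 1]`.
#' @param order `"length-desc"` or `"input"`.
#' @return data.frame, one row per cluster: `cluster_id`, `centroid_id`,
#'   `member_ids` (comma-joined, assignment order), `n_members`,
#'   `representative_ids` (empty until [select_representatives()]).
#' @export
greedy_identity_cluster <- function(sequences, min_identity = 0.9,
                                    order = c("length-desc", "input")) {
  order <- match.arg(order)
  seqs <- as.character(sequences)
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids))
    stopf("'sequences' must have unique names")
  idx <- seq_along(seqs)
  if (order == "length-desc")
    idx <- idx[base::order(-nchar(seqs), idx)]
  centroids <- integer(0)          # indices of founding centroids
  members <- list()
  for (i in idx) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (pairwise_identity(seqs[i], seqs[centroids[ci]]) >= min_identity) {
        members[[ci]] <- c(members[[ci]], i); placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      members[[length(centroids)]] <- i
    }
  }
  data.frame(
    cluster_id = sprintf("SC%04d", seq_along(centroids)),
    centroid_id = ids[centroids],
    member_ids = vapply(members, function(m) join_ids(ids[m]), character(1)),
    n_members = lengths(members),
    representative_ids = "",
    stringsAsFactors = FALSE)
}

#' Select representatives from sequence clusters
#'
#' Clusters with at most `k` members (including singletons) keep all
#' members; larger clusters get `k` members sampled uniformly without
#' replacement under the seed, so selection is reproducible.
#'
#' @param clusters data.frame from [greedy_identity_cluster()].
#' @param k Maximum representatives per cluster.
#' @param seed Integer seed.
#' @return `clusters` with `representative_ids` filled (comma-joined,
#'   sorted).
#' @export
select_representatives <- function(clusters, k = 5L, seed = 1L) {
  if (k < 1) stopf("'k' must be >= 1")
  with_seed(seed, {
    clusters$representative_ids <- vapply(clusters$member_ids, function(m) {
      ids <- split_ids(m)
      if (length(ids) > k) ids <- sample(ids, k)
      join_ids(sort(ids))
    }, character(1), USE.NAMES = FALSE)
    clusters
  })
}

aln_matrix <- function(aln) {
  seqs <- as.character(aln)
  if (length(unique(nchar(seqs))) > 1L)
    stopf("ragged alignment: all rows must have equal length")
  do.call(rbind, strsplit(seqs, ""))
}

#' Trim high-gap columns from an alignment
#'
#' Removes every column whose gap fraction (counting `-` and `.`) exceeds
#' `max_gap_fraction`; row order is preserved and the kept column indices
#' are attached as attribute `kept_columns`. With `max_gap_fraction = 1`
#' the alignment is returned unchanged.
#'
#' @param aln `AAStringSet` (or named character vector) of equal-length
#'   aligned sequences.
#' @param max_gap_fraction Maximum tolerated gap fraction per column.
#' @return Trimmed `AAStringSet` with attribute `kept_columns`.
#' @export
trim_alignment <- function(aln, max_gap_fraction = 0.5) {
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == "-" | m == ".")
  keep <- which(gap_frac <= max_gap_fraction)
  out <- Biostrings::AAStringSet(apply(m[, keep, drop = FALSE], 1L, paste,
                                       collapse = ""))
  names(out) <- names(aln)
  attr(out, "kept_columns") <- keep
  out
}

#' Concatenate two alignment blocks by sequence id
#'
#' Rows are matched by name; a sequence present in only one block gets an
#' all-gap segment for the other (with a warning). Entirely disjoint id
#' sets are an error. The merged width is the sum of the block widths.
#'
#' @param aln1,aln2 `AAStringSet` alignment blocks.
#' @return Merged `AAStringSet` over the union of ids (sorted).
#' @export
concatenate_alignments <- function(aln1, aln2) {
  m1 <- aln_matrix(aln1); m2 <- aln_matrix(aln2)
  n1 <- names(aln1); n2 <- names(aln2)
  if (is.null(n1) || is.null(n2)) stopf("alignment blocks must be named")
  if (!length(intersect(n1, n2)))
    stopf("alignment blocks share no sequence ids")
  all_ids <- sort(union(n1, n2))
  miss <- setdiff(all_ids, intersect(n1, n2))
  if (length(miss))
    warnf("%d sequence(s) missing from one block; gap-filled: %s",
          length(miss), paste(miss, collapse = ", "))
  w1 <- ncol(m1); w2 <- ncol(m2)
  rows <- vapply(all_ids, function(id) {
    s1 <- if (id %in% n1) paste(m1[match(id, n1), ], collapse = "")
          else strrep("-", w1)
    s2 <- if (id %in% n2) paste(m2[match(id, n2), ], collapse = "")
          else strrep("-", w2)
    paste0(s1, s2)
  }, character(1))
  out <- Biostrings::AAStringSet(rows)
  names(out) <- all_ids
  out
}

#' Pairwise distance matrix from a protein alignment
#'
#' Computes, for each sequence pair, the proportion of mismatching sites
#' over alignment columns where both sequences are ungapped (p-distance),
#' optionally with a Poisson correction `-log(1 - p)` for multiple
#' substitutions. Pairs with no shared ungapped column get distance `NA`.
#'
#' @param aln `AAStringSet` (or named character vector) of equal-length
#'   aligned sequences.
#' @param correction `"p"` (raw proportion) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @export
alignment_distances <- function(aln, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  m <- aln_matrix(aln)
  gap <- m == "-" | m == "."
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else NA_real_
    if (correction == "poisson" && !is.na(p))
      p <- if (p >= 1) Inf else -log(1 - p)
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (Saitou-Nei Q criterion with the standard
#' branch-length formulas). Ties in Q are broken by lexicographic order of
#' the joined label pair, so the result is deterministic; negative branch
#' lengths are clamped to 0 and the clamped total recorded in attribute
#' `clamped`. On an exactly additive matrix the generating tree's topology
#' and branch lengths are recovered.
#'
#' @param d Symmetric numeric matrix (or `dist`) with zero diagonal and
#'   labelled rows; `n >= 2`.
#' @return Unrooted ape `phylo` (a 2-leaf input yields the single edge
#'   split evenly around its midpoint node).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("'d' must be a square matrix")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-8) stopf("'d' must be symmetric")
  if (any(diag(d) != 0)) stopf("'d' must have a zero diagonal")
  n <- nrow(d)
  if (n < 2L) stopf("need at least 2 taxa")
  labels <- rownames(d)
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  fmt <- function(x) sprintf("%.17g", x)
  # each active node carries a growing newick fragment
  node_nwk <- as.list(labels)
  names(node_nwk) <- labels
  # tie-break key: the lexicographically smallest leaf under each node
  node_key <- labels
  D <- d
  active <- labels
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- NULL; best_q <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      key <- sort(c(node_key[i], node_key[j]))
      if (Q[i, j] < best_q - 1e-12 ||
          (abs(Q[i, j] - best_q) <= 1e-12 && !is.null(best) &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, key = key); best_q <- Q[i, j]
      }
    }
    i <- best$i; j <- best$j
    bi <- clamp(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- clamp(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    new_nwk <- sprintf("(%s:%s,%s:%s)", node_nwk[[i]], fmt(bi),
                       node_nwk[[j]], fmt(bj))
    new_d <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    node_nwk <- c(node_nwk[keep], new_nwk)
    node_key <- c(node_key[keep], min(best$key))
    D <- D2
    active <- c(active[keep], paste0("U", m))
  }
  if (length(active) == 2L) {
    half <- D[1, 2] / 2
    nwk <- sprintf("(%s:%s,%s:%s);", node_nwk[[1]], fmt(half),
                   node_nwk[[2]], fmt(half))
  } else {
    b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   node_nwk[[1]], fmt(b1), node_nwk[[2]], fmt(b2),
                   node_nwk[[3]], fmt(b3))
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Midpoint rooting
#'
#' Places the root halfway along the longest leaf-to-leaf path, so the two
#' ends of that path are equidistant from the root. A tree whose branch
#' lengths are all zero has no defined midpoint and is an error.
#'
#' @param tree Unrooted ape `phylo` with branch lengths and >= 2 leaves.
#' @return Rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stopf("need at least 2 leaves")
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    stopf("midpoint undefined: tree has no positive branch lengths")
  if (length(tree$tip.label) == 2L) {
    total <- sum(tree$edge.length)
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         tree$tip.label[1], total / 2,
                                         tree$tip.label[2], total / 2)))
  }
  phangorn::midpoint(tree)
}

#' Outgroup rooting
#'
#' Roots the tree on the branch separating the outgroup clade from the
#' rest, placing the root at that branch's midpoint. The outgroup must be
#' separable as a clade in some rooting of the tree; otherwise an error
#' names the offending leaves.
#'
#' @param tree Unrooted ape `phylo`.
#' @param outgroup_leaves Character vector of outgroup tip labels.
#' @return Rooted `phylo`.
#' @export
outgroup_root <- function(tree, outgroup_leaves) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(outgroup_leaves, tree$tip.label)
  if (length(missing))
    stopf("outgroup leaf(s) not in tree: %s", paste(missing, collapse = ", "))
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_leaves, resolve.root = TRUE),
    error = function(e)
      stopf("outgroup {%s} is not separable as a clade: %s",
            paste(outgroup_leaves, collapse = ", "), conditionMessage(e)))
  if (!ape::is.monophyletic(rooted, outgroup_leaves))
    stopf("outgroup {%s} is not separable as a clade",
          paste(outgroup_leaves, collapse = ", "))
  # split the separating branch evenly around the new root
  root_node <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1] == root_node)
  if (length(re) == 2L && !is.null(rooted$edge.length)) {
    total <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- total / 2
  }
  rooted
}

#' Assembly N50 and quality filter
#'
#' N50 is the length of the contig at which the cumulative sum of contig
#' lengths in descending order first reaches at least half the total
#' assembly length; it is invariant to contig order. An assembly passes the
#' filter when its N50 is at or above `threshold` (inclusive).
#'
#' @param assemblies Named list, genome id -> numeric vector of contig
#'   lengths (bp).
#' @param threshold Minimum N50 in bp.
#' @return data.frame `genome_id`, `n50`, `pass`.
#' @export
n50_filter <- function(assemblies, threshold = 50000) {
  if (!length(assemblies) || is.null(names(assemblies)))
    stopf("'assemblies' must be a non-empty named list of contig lengths")
  n50s <- vapply(names(assemblies), function(g) {
    n50(assemblies[[g]])
  }, numeric(1))
  data.frame(genome_id = names(assemblies), n50 = unname(n50s),
             pass = unname(n50s >= threshold), stringsAsFactors = FALSE)
}

#' @rdname n50_filter
#' @param lengths Numeric vector of contig lengths for one assembly.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stopf("empty contig length list")
  if (any(lengths <= 0)) stopf("contig lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}
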