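#' Domain-content distance between two gene clusters
#'
#' `d = 1 - (w_J * J + w_A * AI)` where `J` is the Jaccard index of the two
#' clusters' domain-accession sets and `AI` is the Jaccard index of their
#' sets of unordered adjacent domain pairs taken along each domain string
#' (unordered pairs make the index invariant to strand orientation). The
#' distance is symmetric, zero for identical content and bounded in
#' `[0, 1]`; it is not guaranteed to obey the triangle inequality.
#'
#' Conventions for degenerate content: a cluster with an empty domain
#' string is at distance 1 from any non-empty cluster and at distance 0
#' from another empty one; when neither cluster has two domains (so neither
#' has adjacent pairs) the adjacency term compares as identical.
#'
#' @param a,b One-row cluster data.frames (or character vectors of domain
#'   accessions in string order).
#' @param weights Non-negative `(w_J, w_A)` summing to 1.
#' @return Distance in `[0, 1]`.
#' @export
cluster_distance <- function(a, b, weights = c(0.5, 0.5)) {
  if (length(weights) != 2L || any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stopf("'weights' must be two non-negative values summing to 1")
  da <- domain_vector(a); db <- domain_vector(b)
  if (!length(da) && !length(db)) return(0)
  if (!length(da) || !length(db)) return(1)
  J <- jaccard(unique(da), unique(db))
  pa <- adjacent_pairs(da); pb <- adjacent_pairs(db)
  AI <- if (!length(pa) && !length(pb)) 1 else jaccard(pa, pb)
  unname(1 - (weights[1] * J + weights[2] * AI))
}

domain_vector <- function(x) {
  if (is.data.frame(x)) split_ids(x$domain_string[1L])
  else as.character(x)
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}

# unordered adjacent pairs along the domain string, as canonical strings
adjacent_pairs <- function(d) {
  if (length(d) < 2L) return(character(0))
  a <- d[-length(d)]; b <- d[-1L]
  unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
}

#' Build the cluster similarity network
#'
#' Evaluates [cluster_distance()] for every unordered pair of clusters and
#' emits an edge for each pair at distance `cutoff` or below.
#'
#' @param clusters Cluster data.frame.
#' @param cutoff Maximum distance for an edge, in `[0, 1]`.
#' @param weights Passed to [cluster_distance()].
#' @return data.frame `id_a`, `id_b`, `distance` (id_a < id_b, sorted).
#' @export
build_network <- function(clusters, cutoff = 0.3, weights = c(0.5, 0.5)) {
  if (cutoff < 0 || cutoff > 1) stopf("'cutoff' must lie in [0, 1]")
  n <- nrow(clusters)
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  doms <- lapply(clusters$domain_string, split_ids)
  sets <- lapply(doms, unique)
  pairs <- lapply(doms, adjacent_pairs)
  ids <- clusters$cluster_id
  out <- vector("list", n * (n - 1) / 2); k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- pair_distance(doms[[i]], doms[[j]], sets[[i]], sets[[j]],
                       pairs[[i]], pairs[[j]], weights)
    if (d <= cutoff) {
      k <- k + 1L
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      out[[k]] <- data.frame(id_a = a, id_b = b, distance = d,
                             stringsAsFactors = FALSE)
    }
  }
  if (!k) return(empty)
  edges <- do.call(rbind, out[seq_len(k)])
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

pair_distance <- function(da, db, sa, sb, pa, pb, weights) {
  if (!length(da) && !length(db)) return(0)
  if (!length(da) || !length(db)) return(1)
  AI <- if (!length(pa) && !length(pb)) 1 else jaccard(pa, pb)
  unname(1 - (weights[1] * jaccard(sa, sb) + weights[2] * AI))
}

#' Group clusters into families as network components
#'
#' Gene cluster families (GCFs) are the connected components of the
#' similarity network; clusters without edges form singleton families.
#' Family ids are deterministic: families ordered by their
#' lexicographically smallest member cluster id, numbered `GCF00001` on.
#'
#' @param clusters Cluster data.frame.
#' @param edges Edge data.frame from [build_network()].
#' @return data.frame, one row per family: `family_id`, `n_members`,
#'   `member_cluster_ids` (comma-joined, sorted), `consensus_domains`
#'   (domains present in at least half of the member clusters) and an empty
#'   `categories` column for [classify_families()] to fill.
#' @export
families_from_network <- function(clusters, edges) {
  ids <- clusters$cluster_id
  bad <- setdiff(unique(c(edges$id_a, edges$id_b)), ids)
  if (length(bad))
    stopf("edges reference unknown cluster(s): %s", paste(bad, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[[`, character(1), 1L))]
  dom_sets <- lapply(clusters$domain_string, function(s) unique(split_ids(s)))
  names(dom_sets) <- ids
  rows <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    tab <- table(unlist(dom_sets[m]))
    consensus <- sort(names(tab)[tab >= length(m) / 2])
    data.frame(family_id = sprintf("GCF%05d", i), n_members = length(m),
               member_cluster_ids = join_ids(m),
               consensus_domains = join_ids(consensus),
               categories = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(family_id = character(0), n_members = integer(0),
               member_cluster_ids = character(0), consensus_domains = character(0),
               categories = character(0), stringsAsFactors = FALSE)
}
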