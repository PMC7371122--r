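#' Extract the metabolic gene cluster around one anchor gene
#'
#' Starting from the anchor, the cluster is extended in both directions
#' along the contig while every added gene (i) lies on the anchor's strand
#' and (ii) is separated from its neighbour by an intergenic gap of at most
#' `params$max_intergenic_gap` bp. The gap between consecutive genes is
#' `next_start - prev_end - 1` in 1-based inclusive coordinates; overlapping
#' genes (negative gap) count as gap 0. Extension stops at a strand change,
#' a gap violation, a gene without strand annotation, or the contig end,
#' which makes the returned run maximal.
#'
#' @param genome A `genome_annotation`.
#' @param anchor_gene `gene_id` of the anchor within `genome`.
#' @param params [mgc_params()].
#' @return One-row data.frame describing the cluster: `cluster_id`,
#'   `genome_id`, `contig_id`, `strand`, `span` (`start`, `end`),
#'   `n_members`, `anchor_ids`, `member_ids` (coordinate order) and
#'   `domain_string` (member domains, sorted within a gene, concatenated in
#'   coordinate order).
#' @export
extract_cluster <- function(genome, anchor_gene, params = mgc_params()) {
  stopifnot(inherits(genome, "genome_annotation"))
  f <- genome$features
  hit <- which(f$gene_id == anchor_gene)
  if (length(hit) != 1L)
    stopf("genome %s: unknown anchor gene '%s'", genome$genome_id, anchor_gene)
  contig <- f$contig_id[hit]
  cf <- f[f$contig_id == contig, , drop = FALSE]   # already start-sorted
  i <- which(cf$gene_id == anchor_gene)
  strand <- cf$strand[i]
  if (is.na(strand))
    stopf("genome %s: anchor gene '%s' has no strand annotation",
          genome$genome_id, anchor_gene)
  gap_ok <- function(prev, nxt)
    max(0L, cf$start[nxt] - cf$end[prev] - 1L) <= params$max_intergenic_gap
  lo <- i
  while (lo > 1L && identical(cf$strand[lo - 1L], strand) && gap_ok(lo - 1L, lo))
    lo <- lo - 1L
  hi <- i
  while (hi < nrow(cf) && identical(cf$strand[hi + 1L], strand) && gap_ok(hi, hi + 1L))
    hi <- hi + 1L
  members <- cf[lo:hi, , drop = FALSE]
  cluster_row(genome$genome_id, contig, strand, members, anchor_gene)
}

cluster_row <- function(genome_id, contig, strand, members, anchor_genes) {
  span <- c(min(members$start), max(members$end))
  data.frame(
    cluster_id = sprintf("%s|%s|%d-%d", genome_id, contig, span[1], span[2]),
    genome_id = genome_id, contig_id = contig, strand = strand,
    start = span[1], end = span[2], n_members = nrow(members),
    anchor_ids = join_ids(sort(anchor_genes)),
    member_ids = join_ids(members$gene_id),
    domain_string = join_ids(unlist(gene_domain_list(members))),
    stringsAsFactors = FALSE)
}

#' Extract clusters for every anchor across genomes
#'
#' Runs [extract_cluster()] for each anchor protein. When several anchors
#' fall inside the same maximal run, a single cluster row is emitted whose
#' `anchor_ids` lists all of them, so the output is non-redundant by
#' construction.
#'
#' @param genomes List of `genome_annotation`.
#' @param anchor_set An `anchor_set` from [find_anchors()]; anchor proteins
#'   are resolved to genes through each genome's `protein_id` column.
#' @param params [mgc_params()].
#' @return data.frame of clusters (see [extract_cluster()]), sorted by
#'   `cluster_id`.
#' @export
extract_all <- function(genomes, anchor_set, params = mgc_params()) {
  stopifnot(inherits(anchor_set, "anchor_set"))
  gids <- vapply(genomes, `[[`, character(1), "genome_id")
  names(genomes) <- gids
  unknown <- setdiff(unique(anchor_set$anchors$genome_id), gids)
  if (length(unknown))
    stopf("anchor set references unknown genome(s): %s",
          paste(unknown, collapse = ", "))
  rows <- list()
  for (gid in unique(anchor_set$anchors$genome_id)) {
    g <- genomes[[gid]]
    prots <- anchor_set$anchors$protein_id[anchor_set$anchors$genome_id == gid]
    genes <- g$features$gene_id[match(prots, g$features$protein_id)]
    if (anyNA(genes))
      stopf("genome %s: anchor protein(s) %s not present in the annotation",
            gid, paste(prots[is.na(genes)], collapse = ", "))
    for (gene in genes)
      rows[[length(rows) + 1L]] <- extract_cluster(g, gene, params)
  }
  if (!length(rows)) return(empty_clusters())
  out <- do.call(rbind, rows)
  # anchors sharing one maximal run produce identical cluster ids: merge
  merged <- lapply(split(out, out$cluster_id), function(d) {
    d1 <- d[1L, , drop = FALSE]
    d1$anchor_ids <- join_ids(sort(unique(unlist(lapply(d$anchor_ids, split_ids)))))
    d1
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_clusters <- function() {
  data.frame(cluster_id = character(0), genome_id = character(0),
             contig_id = character(0), strand = character(0),
             start = integer(0), end = integer(0), n_members = integer(0),
             anchor_ids = character(0), member_ids = character(0),
             domain_string = character(0), stringsAsFactors = FALSE)
}

#' Collapse redundant clusters
#'
#' Clusters with an identical key collapse to one representative, the
#' lexicographically smallest `cluster_id`. The key is either the ordered
#' domain string alone, or the gene count plus the ordered domain string;
#' clusters whose domain multisets match but in a different order are NOT
#' collapsed under either key.
#'
#' @param clusters Cluster data.frame.
#' @param key `"domain_string"` or `"gene_count_domain_string"`.
#' @return `list(clusters = <representative rows>, redundancy =
#'   <data.frame cluster_id, representative_id>)`; the redundancy map
#'   covers every input cluster.
#' @export
deduplicate_clusters <- function(clusters,
                                 key = c("domain_string", "gene_count_domain_string")) {
  key <- match.arg(key)
  if (!nrow(clusters))
    return(list(clusters = clusters,
                redundancy = data.frame(cluster_id = character(0),
                                        representative_id = character(0),
                                        stringsAsFactors = FALSE)))
  kv <- switch(key,
               domain_string = clusters$domain_string,
               gene_count_domain_string = paste(clusters$n_members,
                                                clusters$domain_string, sep = "|"))
  rep_of <- tapply(clusters$cluster_id, kv, function(ids) min(ids))
  representative <- unname(rep_of[kv])
  keep <- clusters[clusters$cluster_id %in% representative, , drop = FALSE]
  keep <- keep[order(keep$cluster_id), , drop = FALSE]
  rownames(keep) <- NULL
  list(clusters = keep,
       redundancy = data.frame(cluster_id = clusters$cluster_id,
                               representative_id = representative,
                               stringsAsFactors = FALSE))
}
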