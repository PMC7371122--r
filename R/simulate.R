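#' Copy-number laws for the genome simulator
#'
#' Per-taxon distributions of anchor-gene copies per genome. `constant`
#' always draws `value`; `poisson` draws from a Poisson with mean `lambda`;
#' `nbinom` draws from a negative binomial with dispersion `size` and mean
#' `mu` (over-dispersed counts emulate the strong strain-level variability
#' seen in real flavoenzyme profiles, where copies range from 0 to ~18 per
#' genome).
#'
#' @param type One of "constant", "poisson", "nbinom".
#' @param value,lambda,size,mu Law parameters (see above).
#' @return An object of class `copy_law`.
#' @export
copy_law <- function(type = c("constant", "poisson", "nbinom"),
                     value = 2L, lambda = 2, size = 2, mu = 2) {
  type <- match.arg(type)
  structure(list(type = type, value = as.integer(value), lambda = lambda,
                 size = size, mu = mu), class = "copy_law")
}

draw_copy_law <- function(law, n) {
  switch(law$type,
         constant = rep(law$value, n),
         poisson = stats::rpois(n, law$lambda),
         nbinom = stats::rnbinom(n, size = law$size, mu = law$mu))
}

#' Generate annotated genomes with planted anchor gene clusters
#'
#' Builds synthetic genome annotations in which every anchor gene sits
#' inside a planted same-strand gene run whose internal intergenic gaps are
#' strictly below `params$max_intergenic_gap`, and which is flanked on both
#' sides by a gap above the threshold or a contig end — so each planted
#' cluster is exactly maximal under the extraction rule and recovery can be
#' scored as precision/recall against the returned truth.
#'
#' Cluster architecture is drawn per family: all planted clusters of one
#' family share the same size, strand, anchor position and ordered domain
#' profile
#' (category domains from `category_map` plus family-private filler
#' domains), so clusters of a family have domain-content distance 0 while
#' different families stay well separated. Decoy genes are placed between
#' planted runs, always separated by more than the gap threshold.
#'
#' @param n_genomes Number of genomes.
#' @param taxa List of `list(taxon =, copy_law =)` entries; genomes are
#'   assigned round-robin. Default: one "Clostridia" taxon with a Poisson(2)
#'   copy law.
#' @param cluster_size_range Integer pair: genes per planted cluster
#'   (drawn once per family).
#' @param intra_gap_range Integer pair: intergenic gaps inside planted
#'   clusters (bp); must stay below `params$max_intergenic_gap`.
#' @param sep_range Integer pair: separation between consecutive elements
#'   (clusters/decoys) on a contig; must exceed `params$max_intergenic_gap`.
#' @param gene_length_range Integer pair of gene lengths (bp).
#' @param decoy_rate Mean number of decoy (non-cluster) genes per genome.
#' @param n_families Number of planted cluster families.
#' @param category_map A category map (see [synthetic_category_map()])
#'   supplying substrate-category domains for cluster members.
#' @param n_contigs Contigs per genome.
#' @param contig_length Optional fixed contig length cap; generation fails
#'   if the planted layout does not fit.
#' @param params [mgc_params()]; supplies the gap threshold and required
#'   (anchor) domains.
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return `list(genomes = <list of genome_annotation>, truth =
#'   <simulation_truth>)`. The truth records planted anchors, planted
#'   clusters (with family and category labels), per-gene true domains and
#'   the per-taxon copy laws.
#' @export
generate_genomes <- function(n_genomes = 20,
                             taxa = list(list(taxon = "Clostridia",
                                              copy_law = copy_law("poisson", lambda = 2))),
                             cluster_size_range = c(3L, 8L),
                             intra_gap_range = c(20L, 200L),
                             sep_range = c(600L, 2000L),
                             gene_length_range = c(600L, 1500L),
                             decoy_rate = 30,
                             n_families = 6L,
                             category_map = synthetic_category_map(),
                             n_contigs = 1L,
                             contig_length = NULL,
                             params = mgc_params(),
                             seed = params$rng_seed) {
  if (n_genomes < 1) stopf("'n_genomes' must be >= 1")
  if (cluster_size_range[1] < 1) stopf("cluster sizes must be >= 1")
  if (max(intra_gap_range) >= params$max_intergenic_gap)
    stopf("intra-cluster gaps must stay below max_intergenic_gap (%d bp)",
          params$max_intergenic_gap)
  if (min(sep_range) <= params$max_intergenic_gap)
    stopf("element separation must exceed max_intergenic_gap (%d bp)",
          params$max_intergenic_gap)
  if (n_families < 1) stopf("'n_families' must be >= 1")
  with_seed(seed, {
    fams <- make_family_specs(n_families, cluster_size_range, category_map)
    taxon_of <- vapply(taxa, `[[`, character(1), "taxon")
    genomes <- vector("list", n_genomes)
    anchors <- list(); clusters <- list(); gene_dom <- list()
    for (i in seq_len(n_genomes)) {
      gid <- sprintf("G%03d", i)
      tx <- ((i - 1L) %% length(taxa)) + 1L
      k <- draw_copy_law(taxa[[tx]]$copy_law, 1L)
      g <- build_one_genome(gid, taxon_of[tx], k, fams, intra_gap_range,
                            sep_range, gene_length_range, decoy_rate,
                            n_contigs, contig_length, params)
      genomes[[i]] <- g$genome
      anchors[[gid]] <- g$anchor_genes
      clusters[[gid]] <- g$clusters
      gene_dom[[gid]] <- g$gene_domains
    }
    planted <- do.call(rbind, unname(clusters))
    if (is.null(planted))
      planted <- data.frame(genome_id = character(0), contig_id = character(0),
                            family_label = character(0), category_label = character(0),
                            strand = character(0), start = integer(0), end = integer(0),
                            anchor_gene_id = character(0), gene_ids = character(0),
                            stringsAsFactors = FALSE)
    truth <- structure(list(
      planted_anchors = anchors[vapply(anchors, length, 1L) > 0L],
      planted_clusters = planted,
      gene_domains = do.call(rbind, unname(gene_dom)) %||% data.frame(),
      per_taxon_copy_law = stats::setNames(lapply(taxa, `[[`, "copy_law"), taxon_of),
      family_specs = fams,
      required_domains = params$required_domains
    ), class = "simulation_truth")
    list(genomes = genomes, truth = truth)
  })
}

# one architecture per family: fixed size, anchor position and ordered
# domain profile, so within-family domain-content distance is exactly 0
make_family_specs <- function(n_families, cluster_size_range, category_map) {
  cats <- sort(unique(category_map$category))
  lapply(seq_len(n_families), function(f) {
    size <- if (cluster_size_range[1] == cluster_size_range[2]) cluster_size_range[1]
            else sample(cluster_size_range[1]:cluster_size_range[2], 1L)
    anchor_pos <- if (size == 1L) 1L else sample(seq_len(size), 1L)
    cat_lab <- cats[((f - 1L) %% length(cats)) + 1L]
    cat_doms <- sort(category_map$domain_acc[category_map$category == cat_lab])
    fillers <- sprintf("PF9%02d%02d", f, 1:2)
    n_extra <- size - 1L
    if (n_extra == 0L) {
      profile <- character(0); cat_lab <- NA_character_
    } else if (n_extra == 1L) {
      # too small to carry both a private marker and a category domain;
      # the private filler wins so families stay distinguishable
      profile <- fillers[1L]; cat_lab <- NA_character_
    } else {
      rest <- if (n_extra > 2L)
        sample(c(cat_doms, fillers), n_extra - 2L, replace = TRUE) else character(0)
      profile <- sample(c(cat_doms[1L], fillers[1L], rest))
    }
    list(label = sprintf("FAM%02d", f), size = size, anchor_pos = anchor_pos,
         strand = sample(c("+", "-"), 1L),
         category = cat_lab, profile = profile)
  })
}

build_one_genome <- function(gid, taxon, n_clusters, fams, intra_gap_range,
                             sep_range, gene_length_range, decoy_rate,
                             n_contigs, contig_length, params) {
  n_decoys <- stats::rpois(1L, decoy_rate)
  elements <- c(
    lapply(seq_len(n_clusters), function(j) list(kind = "cluster",
                                                 fam = sample(length(fams), 1L))),
    lapply(seq_len(n_decoys), function(j) list(kind = "decoy")))
  if (length(elements)) elements <- elements[sample(length(elements))]
  contig_of <- if (length(elements))
    sample(seq_len(n_contigs), length(elements), replace = TRUE) else integer(0)
  gene_counter <- 0L
  feats <- list(); cl_rows <- list(); gd_rows <- list(); anchor_genes <- character(0)
  contig_len <- stats::setNames(numeric(n_contigs), sprintf("%s_c%d", gid, seq_len(n_contigs)))
  for (ci in seq_len(n_contigs)) {
    contig_id <- sprintf("%s_c%d", gid, ci)
    cursor <- sample(200:800, 1L)
    for (el in which(contig_of == ci)) {
      e <- elements[[el]]
      if (e$kind == "decoy") {
        gene_counter <- gene_counter + 1L
        len <- sample(gene_length_range[1]:gene_length_range[2], 1L)
        feats[[length(feats) + 1L]] <- data.frame(
          gene_id = sprintf("%s_g%04d", gid, gene_counter),
          contig_id = contig_id, start = cursor, end = cursor + len - 1L,
          strand = sample(c("+", "-"), 1L),
          protein_id = sprintf("%s_p%04d", gid, gene_counter),
          domains = "", stringsAsFactors = FALSE)
        cursor <- cursor + len + sample(sep_range[1]:sep_range[2], 1L)
      } else {
        spec <- fams[[e$fam]]
        strand <- spec$strand
        lens <- sample(gene_length_range[1]:gene_length_range[2], spec$size,
                       replace = TRUE)
        gaps <- if (spec$size > 1L)
          sample(intra_gap_range[1]:intra_gap_range[2], spec$size - 1L,
                 replace = TRUE) else integer(0)
        starts <- integer(spec$size); ends <- integer(spec$size)
        pos <- cursor
        for (p in seq_len(spec$size)) {
          starts[p] <- pos; ends[p] <- pos + lens[p] - 1L
          if (p < spec$size) pos <- ends[p] + gaps[p] + 1L
        }
        # transcription order: coordinate order on '+', reversed on '-'
        tx_order <- if (strand == "+") seq_len(spec$size) else rev(seq_len(spec$size))
        dom_of <- vector("list", spec$size)
        extra_i <- 0L
        for (tp in seq_len(spec$size)) {
          coord_idx <- tx_order[tp]
          if (tp == spec$anchor_pos) {
            dom_of[[coord_idx]] <- params$required_domains
          } else {
            extra_i <- extra_i + 1L
            dom_of[[coord_idx]] <- spec$profile[extra_i]
          }
        }
        ids <- sprintf("%s_g%04d", gid, gene_counter + seq_len(spec$size))
        pids <- sprintf("%s_p%04d", gid, gene_counter + seq_len(spec$size))
        gene_counter <- gene_counter + spec$size
        anchor_coord <- tx_order[spec$anchor_pos]
        anchor_genes <- c(anchor_genes, ids[anchor_coord])
        feats[[length(feats) + 1L]] <- data.frame(
          gene_id = ids, contig_id = contig_id, start = starts, end = ends,
          strand = strand, protein_id = pids,
          domains = vapply(dom_of, function(d) join_ids(sort(d)), character(1)),
          stringsAsFactors = FALSE)
        cl_rows[[length(cl_rows) + 1L]] <- data.frame(
          genome_id = gid, contig_id = contig_id, family_label = spec$label,
          category_label = spec$category, strand = strand,
          start = starts[1L], end = ends[spec$size],
          anchor_gene_id = ids[anchor_coord], gene_ids = join_ids(ids),
          stringsAsFactors = FALSE)
        gd_rows[[length(gd_rows) + 1L]] <- data.frame(
          genome_id = gid, gene_id = rep(ids, lengths(dom_of)),
          protein_id = rep(pids, lengths(dom_of)),
          domain_acc = unlist(dom_of), stringsAsFactors = FALSE)
        cursor <- ends[spec$size] + 1L + sample(sep_range[1]:sep_range[2], 1L)
      }
    }
    contig_len[contig_id] <- cursor + sample(200:800, 1L)
    if (!is.null(contig_length)) {
      if (contig_len[contig_id] > contig_length)
        stopf("genome %s: planted layout (%d bp) exceeds contig_length %d",
              gid, as.integer(contig_len[contig_id]), as.integer(contig_length))
      contig_len[contig_id] <- contig_length
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()
  list(genome = genome_annotation(gid, features, taxon, contig_len),
       anchor_genes = anchor_genes,
       clusters = if (length(cl_rows)) do.call(rbind, cl_rows) else NULL,
       gene_domains = if (length(gd_rows)) do.call(rbind, gd_rows) else NULL)
}

#' Generate a domain hit table matching a simulation truth
#'
#' Every planted gene receives hits for its true domains (anchors get both
#' required domains) with E-values drawn from `e_law`. Decoy proteins can
#' receive noise: with probability `single_domain_rate` exactly one of the
#' required domains (these must never be called anchors downstream), and
#' with probability `false_hit_rate` a spurious hit to a domain outside the
#' category map.
#'
#' @param genomes List of `genome_annotation` from [generate_genomes()].
#' @param truth The matching `simulation_truth`.
#' @param e_law Function `n -> n` E-values for true hits; the default draws
#'   log-uniform in `[1e-20, 1e-6]`, below the 1e-5 anchor threshold.
#' @param false_hit_rate,single_domain_rate Per-decoy noise probabilities.
#' @param seed Integer seed.
#' @return data.frame of hits (`protein_id`, `genome_id`, `domain_acc`,
#'   `e_value`, `score`), deterministically sorted.
#' @export
generate_domain_hits <- function(genomes, truth,
                                 e_law = function(n) 10^stats::runif(n, -20, -6),
                                 false_hit_rate = 0, single_domain_rate = 0,
                                 seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  gids <- vapply(genomes, `[[`, character(1), "genome_id")
  tgids <- unique(truth$planted_clusters$genome_id)
  if (!all(tgids %in% gids))
    stopf("truth references genomes absent from 'genomes': %s",
          paste(setdiff(tgids, gids), collapse = ", "))
  with_seed(seed, {
    out <- list()
    gd <- truth$gene_domains
    if (!is.null(gd) && nrow(gd)) {
      out[[1L]] <- data.frame(
        protein_id = gd$protein_id, genome_id = gd$genome_id,
        domain_acc = gd$domain_acc, e_value = e_law(nrow(gd)),
        stringsAsFactors = FALSE)
    }
    planted_genes <- if (!is.null(gd) && nrow(gd))
      paste(gd$genome_id, gd$gene_id) else character(0)
    for (g in genomes) {
      f <- g$features
      decoy <- f[!paste(g$genome_id, f$gene_id) %in% planted_genes, , drop = FALSE]
      if (!nrow(decoy)) next
      one_dom <- stats::runif(nrow(decoy)) < single_domain_rate
      if (any(one_dom)) {
        out[[length(out) + 1L]] <- data.frame(
          protein_id = decoy$protein_id[one_dom], genome_id = g$genome_id,
          domain_acc = sample(truth$required_domains, sum(one_dom), replace = TRUE),
          e_value = e_law(sum(one_dom)), stringsAsFactors = FALSE)
      }
      false_hit <- stats::runif(nrow(decoy)) < false_hit_rate
      if (any(false_hit)) {
        out[[length(out) + 1L]] <- data.frame(
          protein_id = decoy$protein_id[false_hit], genome_id = g$genome_id,
          domain_acc = sprintf("PF98%03d", sample(1:50, sum(false_hit), replace = TRUE)),
          e_value = 10^stats::runif(sum(false_hit), -12, -2),
          stringsAsFactors = FALSE)
      }
    }
    hits <- if (length(out)) do.call(rbind, out) else empty_hits()[, 1:4]
    hits$score <- round(-log10(hits$e_value) * 3, 1)
    hits <- hits[order(hits$genome_id, hits$protein_id, hits$domain_acc,
                       hits$e_value), , drop = FALSE]
    rownames(hits) <- NULL
    hits
  })
}

#' Generate protein sequence sets with planted identity structure
#'
#' Produces `n` amino-acid sequences partitioned into `n_families` planted
#' families. A family centroid is derived from a common ancestor by per-site
#' substitution at a rate solved (numerically, accounting for chance
#' matches at 1/19) so that expected between-family pairwise identity is
#' `between_identity`; members mutate from their centroid likewise towards
#' `within_identity`.
#'
#' @param n Number of sequences.
#' @param n_families Number of planted families (sizes as even as possible).
#' @param within_identity,between_identity Target expected pairwise
#'   identities; `0 <= between < within <= 1`.
#' @param length Sequence length (sites).
#' @param seed Integer seed.
#' @return `list(sequences = <Biostrings::AAStringSet>, truth =
#'   <data.frame seq_id, family>)`.
#' @export
generate_sequence_set <- function(n, n_families, within_identity,
                                  between_identity, length = 300L, seed = 1L) {
  if (n < 1 || n_families < 1 || n_families > n)
    stopf("need 1 <= n_families <= n")
  if (!(between_identity >= 0 && between_identity < within_identity &&
        within_identity <= 1))
    stopf("need 0 <= between_identity < within_identity <= 1")
  if (length < 1) stopf("'length' must be >= 1")
  if (n_families > 1 && between_identity < 1 / 19)
    stopf(paste("between_identity %.3f is unreachable: unrelated sequences over",
                "a 20-letter alphabet share about 1/19 of sites by chance"),
          between_identity)
  with_seed(seed, {
    aa <- Biostrings::AA_STANDARD
    ancestor <- sample(aa, length, replace = TRUE)
    m_between <- if (n_families > 1L) rate_for_identity(between_identity) else 0
    m_within <- rate_for_identity(within_identity)
    sizes <- rep(n %/% n_families, n_families)
    if (n %% n_families) sizes[seq_len(n %% n_families)] <-
      sizes[seq_len(n %% n_families)] + 1L
    seqs <- character(0); fam <- character(0); idx <- 0L
    for (f in seq_len(n_families)) {
      centroid <- if (n_families == 1L) ancestor else mutate_seq(ancestor, m_between, aa)
      for (j in seq_len(sizes[f])) {
        idx <- idx + 1L
        member <- mutate_seq(centroid, m_within, aa)
        seqs <- c(seqs, paste(member, collapse = ""))
        fam <- c(fam, sprintf("FAM%02d", f))
      }
    }
    ids <- sprintf("S%03d", seq_len(n))
    list(sequences = stats::setNames(Biostrings::AAStringSet(seqs), ids),
         truth = data.frame(seq_id = ids, family = fam, stringsAsFactors = FALSE))
  })
}

# per-site substitution rate m such that two sequences independently
# mutated from a common source at rate m have expected identity `target`:
# identity(m) = (1-m)^2 + m^2/19  (a substitution always changes the residue;
# two substitutions agree by chance with probability 1/19)
rate_for_identity <- function(target) {
  if (target >= 1) return(0)
  f <- function(m) (1 - m)^2 + m^2 / 19 - target
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

mutate_seq <- function(x, rate, alphabet) {
  hit <- stats::runif(length(x)) < rate
  if (any(hit)) {
    x[hit] <- vapply(x[hit], function(res)
      sample(setdiff(alphabet, res), 1L), character(1))
  }
  x
}

#' Patristic distance matrix of a tree
#'
#' Returns the matrix of leaf-to-leaf path-length distances of a tree with
#' positive branch lengths; symmetric with zero diagonal. Used as the exact
#' additive input on which neighbor joining must recover the tree.
#'
#' @param tree An ape `phylo` with positive branch lengths.
#' @return Numeric matrix indexed by tip labels.
#' @export
generate_additive_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stopf("tree must have positive branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d[sort(rownames(d)), sort(colnames(d))]
}
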