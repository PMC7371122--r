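#' Run the full synthetic pipeline end to end
#'
#' Simulates genomes, generates the domain hit table, finds anchors,
#' profiles copy numbers per taxon, extracts clusters, builds the
#' similarity network, groups families and classifies them — writing every
#' stage's table into `out_dir`. All randomness derives from `seed`, so two
#' runs with the same seed produce byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_genomes,taxa,n_families,category_map Passed to
#'   [generate_genomes()].
#' @param noise `list(false_hit_rate =, single_domain_rate =)` for
#'   [generate_domain_hits()].
#' @param params [mgc_params()].
#' @return Invisibly, a list with `paths` (the written files) and the
#'   in-memory stage results (`genomes`, `truth`, `hits`, `anchors`,
#'   `counts`, `profile`, `clusters`, `edges`, `families`, `summary`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_genomes = 20,
                         taxa = list(list(taxon = "Clostridia",
                                          copy_law = copy_law("poisson", lambda = 2))),
                         n_families = 6L,
                         category_map = synthetic_category_map(),
                         noise = list(false_hit_rate = 0, single_domain_rate = 0),
                         params = mgc_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genomes(n_genomes = n_genomes, taxa = taxa,
                          n_families = n_families, category_map = category_map,
                          params = params, seed = seed)
  hits <- generate_domain_hits(sim$genomes, sim$truth,
                               false_hit_rate = noise$false_hit_rate,
                               single_domain_rate = noise$single_domain_rate,
                               seed = seed + 1L)
  paths <- list(
    hits = file.path(out_dir, "hits.tsv"),
    anchors = file.path(out_dir, "anchors.tsv"),
    profile = file.path(out_dir, "profile.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    edges = file.path(out_dir, "edges.tsv"),
    families = file.path(out_dir, "families.tsv"),
    summary = file.path(out_dir, "category_summary.tsv"))
  for (g in sim$genomes)
    write_genome_annotation(g, file.path(out_dir, paste0(g$genome_id, ".gff3")))
  write_domain_hits(hits, paths$hits)
  anchors <- find_anchors(hits, params)
  utils::write.table(anchors$anchors, paths$anchors, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- copy_number_table(anchors, sim$genomes)
  taxonomy <- stats::setNames(vapply(sim$genomes, `[[`, character(1), "taxon"),
                              vapply(sim$genomes, `[[`, character(1), "genome_id"))
  profile <- taxon_profile(counts, taxonomy)
  write_profile_table(profile, paths$profile)
  genomes_dom <- attach_domains(sim$genomes, hits, params)
  clusters <- extract_all(genomes_dom, anchors, params)
  write_cluster_table(clusters, paths$clusters)
  edges <- build_network(clusters, cutoff = params$network_cutoff,
                         weights = params$network_weights)
  write_edge_table(edges, paths$edges)
  families <- families_from_network(clusters, edges)
  cls <- classify_families(families, clusters, category_map)
  write_family_table(cls$families, paths$families)
  utils::write.table(cls$summary, paths$summary, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, genomes = sim$genomes, truth = sim$truth,
                 hits = hits, anchors = anchors, counts = counts,
                 profile = profile, clusters = clusters, edges = edges,
                 families = cls$families, summary = cls$summary))
}
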