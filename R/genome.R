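#' Construct a genome annotation
#'
#' The shared in-memory representation of one annotated genome: a feature
#' table of protein-coding genes plus optional contig lengths and a free-form
#' taxon label. Coordinates are 1-based inclusive on every input route.
#'
#' @param genome_id Genome/assembly identifier.
#' @param features data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` ("+", "-", or NA when unannotated), `protein_id`, and
#'   optionally `domains` (comma-joined Pfam accessions, "" when none).
#' @param taxon Free-form lineage label (e.g. "Clostridia").
#' @param contig_lengths Named numeric vector of contig lengths in bp;
#'   may cover only some contigs.
#'
#' @return An object of class `genome_annotation`; features are sorted by
#'   contig then start.
#' @export
genome_annotation <- function(genome_id, features, taxon = NA_character_,
                              contig_lengths = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  need <- c("gene_id", "contig_id", "start", "end", "strand", "protein_id")
  if (!is.data.frame(features) || !all(need %in% names(features)))
    stopf("features must be a data.frame with columns %s", paste(need, collapse = ", "))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"domains" %in% names(features)) features$domains <- ""
  features <- features[, c(need, "domains"), drop = FALSE]
  features$domains[is.na(features$domains)] <- ""
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (any(is.na(features$start)) || any(is.na(features$end)))
      stopf("genome %s: non-numeric coordinates", genome_id)
    bad <- which(features$start > features$end)
    if (length(bad))
      stopf("genome %s: start > end for gene(s) %s", genome_id,
            paste(features$gene_id[bad], collapse = ", "))
    if (!all(features$strand %in% c("+", "-") | is.na(features$strand)))
      stopf("genome %s: strand must be '+', '-' or NA", genome_id)
    if (anyDuplicated(features$gene_id))
      stopf("genome %s: duplicated gene_id", genome_id)
    features <- features[order(features$contig_id, features$start, features$end), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  if (!is.null(contig_lengths)) {
    if (is.null(names(contig_lengths)))
      stopf("contig_lengths must be a named vector")
    contig_lengths <- vapply(contig_lengths, as.numeric, numeric(1))
    known <- features$contig_id %in% names(contig_lengths)
    over <- known & features$end > contig_lengths[features$contig_id]
    if (any(over, na.rm = TRUE))
      stopf("genome %s: feature end beyond contig length (%s)", genome_id,
            paste(features$gene_id[which(over)], collapse = ", "))
  }
  structure(list(genome_id = genome_id, taxon = as.character(taxon),
                 features = features, contig_lengths = contig_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("Genome %s (%s): %d gene(s) on %d contig(s)\n",
              x$genome_id, ifelse(is.na(x$taxon), "taxon unknown", x$taxon),
              nrow(x$features), length(unique(x$features$contig_id))))
  invisible(x)
}

# per-gene domain accessions as a list of character vectors, each sorted
# by accession (the deterministic within-gene order used for domain strings)
gene_domain_list <- function(features) {
  lapply(features$domains, function(d) sort(split_ids(d)))
}

#' Attach domain annotations to genome features
#'
#' Fills the `domains` column of each genome's feature table from a domain
#' hit table, keeping hits at or below the E-value threshold. Within a gene,
#' accessions are stored sorted and de-duplicated; this is the order used to
#' build cluster domain strings.
#'
#' @param genomes A `genome_annotation` or list of them.
#' @param hits data.frame of domain hits (see [read_domain_hits()]).
#' @param params [mgc_params()] providing `e_threshold`.
#' @return The genome(s) with `domains` filled.
#' @export
attach_domains <- function(genomes, hits, params = mgc_params()) {
  single <- inherits(genomes, "genome_annotation")
  if (single) genomes <- list(genomes)
  keep <- hits[hits$e_value <= params$e_threshold, , drop = FALSE]
  key <- paste(keep$genome_id, keep$protein_id, sep = "\r")
  by_prot <- split(keep$domain_acc, key)
  genomes <- lapply(genomes, function(g) {
    k <- paste(g$genome_id, g$features$protein_id, sep = "\r")
    g$features$domains <- vapply(k, function(ki) {
      join_ids(sort(unique(by_prot[[ki]] %||% character(0))))
    }, character(1), USE.NAMES = FALSE)
    g
  })
  if (single) genomes[[1L]] else genomes
}
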