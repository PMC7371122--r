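#' Tabular pipeline outputs
#'
#' All pipeline stages exchange plain TSV files with a header row and a
#' documented, deterministic column order; list-valued fields (member ids,
#' domain strings, categories) are comma-joined in a stable order. Each
#' writer sorts its rows so a fixed input always yields a byte-identical
#' file, and each table round-trips through its paired reader.
#'
#' @param clusters,families,profiles,edges data.frames as produced by the
#'   corresponding pipeline stage.
#' @param path Output (or input) file path.
#' @return Writers return `path` invisibly; readers return the data.frame.
#' @name pipeline_tables
NULL

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stopf("cannot write %s: %s", path, conditionMessage(e)))
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = NA)
}

#' @rdname pipeline_tables
#' @export
write_cluster_table <- function(clusters, path) {
  cols <- c("cluster_id", "genome_id", "contig_id", "strand", "start", "end",
            "n_members", "anchor_ids", "member_ids", "domain_string")
  clusters <- clusters[order(clusters$cluster_id), cols, drop = FALSE]
  write_tsv(clusters, path)
}

#' @rdname pipeline_tables
#' @export
read_cluster_table <- function(path) {
  tab <- read_tsv(path)
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  tab$n_members <- as.integer(tab$n_members)
  for (col in c("anchor_ids", "member_ids", "domain_string"))
    tab[[col]] <- ifelse(is.na(tab[[col]]), "", as.character(tab[[col]]))
  tab
}

#' @rdname pipeline_tables
#' @export
write_family_table <- function(families, path) {
  cols <- c("family_id", "n_members", "member_cluster_ids",
            "consensus_domains", "categories", "annotations")
  cols <- intersect(cols, names(families))
  families <- families[order(families$family_id), cols, drop = FALSE]
  write_tsv(families, path)
}

#' @rdname pipeline_tables
#' @export
read_family_table <- function(path) {
  tab <- read_tsv(path)
  tab$n_members <- as.integer(tab$n_members)
  for (col in intersect(c("member_cluster_ids", "consensus_domains",
                          "categories", "annotations"), names(tab)))
    tab[[col]] <- ifelse(is.na(tab[[col]]), "", as.character(tab[[col]]))
  tab
}

#' @rdname pipeline_tables
#' @export
write_profile_table <- function(profiles, path) {
  cols <- c("taxon", "n_genomes", "n_encoding", "prevalence",
            "mean_copies", "sd_copies", "max_copies")
  profiles <- profiles[order(profiles$taxon), cols, drop = FALSE]
  profiles$prevalence <- sprintf("%.6f", profiles$prevalence)
  profiles$mean_copies <- ifelse(is.na(profiles$mean_copies), "NA",
                                 sprintf("%.6f", profiles$mean_copies))
  profiles$sd_copies <- ifelse(is.na(profiles$sd_copies), "NA",
                               sprintf("%.6f", profiles$sd_copies))
  write_tsv(profiles, path)
}

#' @rdname pipeline_tables
#' @export
read_profile_table <- function(path) {
  tab <- read_tsv(path)
  for (col in c("prevalence", "mean_copies", "sd_copies"))
    tab[[col]] <- as.numeric(tab[[col]])
  for (col in c("n_genomes", "n_encoding", "max_copies"))
    tab[[col]] <- as.integer(tab[[col]])
  tab
}

#' @rdname pipeline_tables
#' @export
write_edge_table <- function(edges, path) {
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  edges$distance <- sprintf("%.6f", edges$distance)
  write_tsv(edges, path)
}

#' @rdname pipeline_tables
#' @export
read_edge_table <- function(path) {
  tab <- read_tsv(path)
  tab$distance <- as.numeric(tab$distance)
  tab
}
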