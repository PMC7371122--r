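#' Read a genome annotation from GFF3 or a feature table
#'
#' GFF3 files are parsed with rtracklayer; contig lengths are taken from
#' `##sequence-region` pragma lines when present. The feature-table dialect
#' is a tab-delimited file with a header row and columns `contig_id`,
#' `start`, `end`, `strand`, `gene_id`, `protein_id` (1-based inclusive
#' coordinates, matching the GenBank convention). Both routes normalise to
#' the same 1-based inclusive representation.
#'
#' Features whose strand is unannotated are skipped with a warning; a record
#' with `start > end` or a malformed line raises a parse error naming the
#' offending line.
#'
#' @param path File path.
#' @param format `"gff3"` or `"feature-table"`.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @param taxon Optional taxon label.
#' @param feature_types GFF3 `type` values retained (default CDS records).
#' @return A [genome_annotation()].
#' @export
read_genome_annotation <- function(path,
                                   format = c("gff3", "feature-table"),
                                   genome_id = NULL, taxon = NA_character_,
                                   feature_types = "CDS") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "gff3") {
    read_gff3_annotation(path, genome_id, taxon, feature_types)
  } else {
    read_feature_table(path, genome_id, taxon)
  }
}

read_gff3_annotation <- function(path, genome_id, taxon, feature_types) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stopf("%s: malformed GFF3 record at line %d (expected >= 8 tab-separated fields)",
            path, i)
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e))
      stopf("%s: non-numeric coordinates at line %d", path, i)
    if (s > e)
      stopf("%s: start > end at line %d", path, i)
  }
  # contig lengths from pragma lines: ##sequence-region <id> <start> <end>
  prag <- grep("^##sequence-region", lines, value = TRUE)
  contig_lengths <- NULL
  if (length(prag)) {
    parts <- strsplit(trimws(prag), "\\s+")
    ok <- vapply(parts, length, 1L) >= 4L
    parts <- parts[ok]
    if (length(parts)) {
      contig_lengths <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
      names(contig_lengths) <- vapply(parts, `[[`, character(1), 2L)
    }
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("%s: GFF3 parse error: %s", path,
                                           conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  gr <- gr[as.character(mc$type) %in% feature_types]
  if (length(gr) == 0L)
    return(genome_annotation(genome_id, empty_features(), taxon, contig_lengths))
  mc <- S4Vectors::mcols(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- NA_character_
  gid <- as.character(mc$ID %||% rep(NA_character_, length(gr)))
  miss <- is.na(gid) | !nzchar(gid)
  if (any(miss)) gid[miss] <- sprintf("%s_f%04d", genome_id, which(miss))
  pid <- if ("protein_id" %in% names(mc)) as.character(mc$protein_id) else gid
  pid[is.na(pid) | !nzchar(pid)] <- gid[is.na(pid) | !nzchar(pid)]
  dom <- if ("domains" %in% names(mc)) {
    vapply(mc$domains, function(d) join_ids(unlist(d)), character(1))
  } else ""
  feats <- data.frame(
    gene_id = gid,
    contig_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = strand, protein_id = pid, domains = dom,
    stringsAsFactors = FALSE)
  nostrand <- is.na(feats$strand)
  if (any(nostrand)) {
    warnf("%s: skipped %d feature(s) without strand annotation", path, sum(nostrand))
    feats <- feats[!nostrand, , drop = FALSE]
  }
  genome_annotation(genome_id, feats, taxon, contig_lengths)
}

read_feature_table <- function(path, genome_id, taxon) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "start", "end", "strand", "gene_id", "protein_id")
  if (!all(need %in% names(tab)))
    stopf("%s: feature table must have columns %s", path, paste(need, collapse = ", "))
  bad <- which(suppressWarnings(as.numeric(tab$start)) >
               suppressWarnings(as.numeric(tab$end)))
  if (length(bad))
    stopf("%s: start > end at data line %d", path, bad[1L])
  tab$strand[!tab$strand %in% c("+", "-")] <- NA
  nostrand <- is.na(tab$strand)
  if (any(nostrand)) {
    warnf("%s: skipped %d feature(s) without strand annotation", path, sum(nostrand))
    tab <- tab[!nostrand, , drop = FALSE]
  }
  if (!"domains" %in% names(tab)) tab$domains <- ""
  genome_annotation(genome_id, tab, taxon)
}

empty_features <- function() {
  data.frame(gene_id = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             protein_id = character(0), domains = character(0),
             stringsAsFactors = FALSE)
}

#' Write a genome annotation as GFF3
#'
#' Emits `##sequence-region` pragmas for contigs with known lengths and one
#' CDS line per feature with `ID`, `protein_id` and (when present) `domains`
#' attributes. Output is deterministic: features in contig/start order,
#' fixed attribute order.
#'
#' @param genome A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_annotation <- function(genome, path) {
  stopifnot(inherits(genome, "genome_annotation"))
  f <- genome$features
  lines <- "##gff-version 3"
  if (!is.null(genome$contig_lengths)) {
    cl <- genome$contig_lengths[order(names(genome$contig_lengths))]
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", names(cl), as.integer(cl)))
  }
  if (nrow(f)) {
    attrs <- sprintf("ID=%s;protein_id=%s", f$gene_id, f$protein_id)
    hasdom <- nzchar(f$domains)
    attrs[hasdom] <- paste0(attrs[hasdom], ";domains=", f$domains[hasdom])
    lines <- c(lines, sprintf("%s\tfesmgc\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              f$contig_id, f$start, f$end, f$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
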