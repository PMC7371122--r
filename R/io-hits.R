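#' Read an hmmsearch-style domain hit table
#'
#' Accepts whitespace-delimited tables in the hmmsearch per-sequence
#' (`--tblout`) or per-domain (`--domtblout`) column layout, with the
#' sequence-level E-value read from the standard column position of the
#' detected dialect. Lines starting with `#` are ignored; extra columns are
#' ignored, so either dialect (or a minimal 5-column table) parses.
#'
#' The dialect is detected per line: when the third field is an integer the
#' row is treated as domtblout (target length in field 3, query accession in
#' field 5, sequence E-value in field 7), otherwise as tblout (query
#' accession in field 4, sequence E-value in field 5). Pfam accession
#' version suffixes (e.g. `PF00724.21`) are stripped.
#'
#' hmmsearch tables carry no genome column, so the genome is taken from (in
#' order of precedence) `genome_map[protein_id]`, the `genome_id` argument,
#' or the free-text description field when it holds a single token (the
#' convention used by [write_domain_hits()]).
#'
#' @param path File path.
#' @param genome_id Single genome id for all rows (per-genome hit files).
#' @param genome_map Named character vector, protein id -> genome id.
#' @return data.frame with columns `protein_id`, `genome_id`, `domain_acc`,
#'   `e_value`, `score`.
#' @export
read_domain_hits <- function(path, genome_id = NA_character_, genome_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(empty_hits())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 5L)
      stopf("%s: line %d has fewer than 5 fields", path, i)
    third_int <- grepl("^[0-9]+$", f[3])
    if (third_int && length(f) >= 7L) {      # domtblout layout
      acc <- if (f[5] != "-") f[5] else f[4]
      ev <- f[7]; sc <- if (length(f) >= 8L) f[8] else NA
      desc_from <- 23L
    } else {                                 # tblout layout
      acc <- if (f[4] != "-") f[4] else f[3]
      ev <- f[5]; sc <- if (length(f) >= 6L) f[6] else NA
      desc_from <- 19L
    }
    e_value <- suppressWarnings(as.numeric(ev))
    if (is.na(e_value))
      stopf("%s: non-numeric E-value '%s' at line %d", path, ev, i)
    desc <- if (length(f) >= desc_from) f[desc_from] else NA_character_
    list(protein_id = f[1], domain_acc = sub("\\.[0-9]+$", "", acc),
         e_value = e_value,
         score = suppressWarnings(as.numeric(sc)), desc = desc)
  })
  hits <- data.frame(
    protein_id = vapply(rows, `[[`, character(1), "protein_id"),
    genome_id = NA_character_,
    domain_acc = vapply(rows, `[[`, character(1), "domain_acc"),
    e_value = vapply(rows, `[[`, numeric(1), "e_value"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  desc <- vapply(rows, function(r) r$desc %||% NA_character_, character(1))
  hits$genome_id <- if (!is.null(genome_map)) {
    unname(genome_map[hits$protein_id])
  } else if (!is.na(genome_id)) {
    genome_id
  } else {
    desc
  }
  if (any(hits$e_value <= 0))
    stopf("%s: E-values must be positive", path)
  hits
}

empty_hits <- function() {
  data.frame(protein_id = character(0), genome_id = character(0),
             domain_acc = character(0), e_value = numeric(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Write a domain hit table in hmmsearch tblout layout
#'
#' Emits the 18 fixed tblout columns (unused ones as `-` or 0) followed by
#' the description field holding the genome id, so the file round-trips
#' through [read_domain_hits()] without extra metadata. Rows are sorted by
#' genome, protein, then accession; output is deterministic.
#'
#' @param hits data.frame as returned by [read_domain_hits()] or
#'   [generate_domain_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  hits <- hits[order(hits$genome_id, hits$protein_id, hits$domain_acc,
                     hits$e_value), , drop = FALSE]
  score <- ifelse(is.na(hits$score), 0, hits$score)
  lines <- c(
    "# target name - query name accession E-value score bias [fixed tblout layout] description",
    sprintf("%s - %s %s %s %.1f 0.0 %s 0.0 0.0 1 1 0 0 1 1 1 1 %s",
            hits$protein_id, hits$domain_acc, hits$domain_acc,
            format(hits$e_value, scientific = TRUE, digits = 3),
            score, format(hits$e_value, scientific = TRUE, digits = 3),
            hits$genome_id))
  writeLines(lines, path)
  invisible(path)
}
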