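#' Identify dual-domain anchor proteins
#'
#' A protein is an anchor if, for every accession in
#' `params$required_domains`, it has at least one hit with sequence E-value
#' at or below `params$e_threshold` (inclusive, so a hit at exactly the
#' threshold counts). Multiple hits of one protein to the same domain count
#' once; with the default domain pair this is the joint
#' Oxidored_FMN + Pyr_redox_2 rule defining the Fe-S flavoenzyme
#' superfamily.
#'
#' @param hits data.frame of domain hits ([read_domain_hits()] /
#'   [generate_domain_hits()]).
#' @param params [mgc_params()].
#' @return An object of class `anchor_set`: `anchors` (data.frame
#'   `genome_id`, `protein_id`, sorted) and `params` (the provenance).
#' @export
find_anchors <- function(hits, params = mgc_params()) {
  if (!inherits(params, "mgc_params")) stopf("'params' must be an mgc_params object")
  req <- params$required_domains
  if (length(req) == 0L) stopf("'required_domains' must be non-empty")
  keep <- hits$e_value <= params$e_threshold & hits$domain_acc %in% req
  sub <- unique(hits[keep, c("genome_id", "protein_id", "domain_acc"), drop = FALSE])
  if (nrow(sub)) {
    key <- paste(sub$genome_id, sub$protein_id, sep = "\r")
    ndom <- tapply(sub$domain_acc, key, function(d) length(unique(d)))
    ok <- names(ndom)[ndom == length(req)]
    parts <- strsplit(ok, "\r", fixed = TRUE)
    anchors <- data.frame(genome_id = vapply(parts, `[[`, character(1), 1L),
                          protein_id = vapply(parts, `[[`, character(1), 2L),
                          stringsAsFactors = FALSE)
    anchors <- anchors[order(anchors$genome_id, anchors$protein_id), , drop = FALSE]
    rownames(anchors) <- NULL
  } else {
    anchors <- data.frame(genome_id = character(0), protein_id = character(0),
                          stringsAsFactors = FALSE)
  }
  structure(list(anchors = anchors, params = params), class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Anchor set: %d protein(s) in %d genome(s) [%s, E <= %g]\n",
              nrow(x$anchors), length(unique(x$anchors$genome_id)),
              paste(x$params$required_domains, collapse = " + "),
              x$params$e_threshold))
  invisible(x)
}

#' Per-genome anchor copy numbers
#'
#' Counts distinct anchor proteins per genome assembly (the copy-number
#' metric); genomes without anchors are reported with count 0, so the sum
#' of counts equals the total number of anchors.
#'
#' @param anchor_set An `anchor_set` from [find_anchors()].
#' @param genomes List of `genome_annotation` covering every genome the
#'   anchors refer to.
#' @return data.frame `genome_id`, `copy_number`, one row per genome,
#'   sorted by genome id.
#' @export
copy_number_table <- function(anchor_set, genomes) {
  stopifnot(inherits(anchor_set, "anchor_set"))
  gids <- vapply(genomes, `[[`, character(1), "genome_id")
  unknown <- setdiff(unique(anchor_set$anchors$genome_id), gids)
  if (length(unknown))
    stopf("anchors reference genome(s) not in 'genomes': %s",
          paste(unknown, collapse = ", "))
  counts <- table(factor(anchor_set$anchors$genome_id, levels = sort(gids)))
  data.frame(genome_id = names(counts), copy_number = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-taxon copy-number and prevalence profile
#'
#' Mean, sample standard deviation (n-1 denominator) and maximum of copy
#' numbers are computed over encoding genomes only — genomes without any
#' anchor are excluded from the copy statistics but counted in the
#' prevalence denominator, so both views of a taxon are reported. The
#' standard deviation is `NA` when fewer than two genomes encode an anchor,
#' and mean/max are `NA` when none does.
#'
#' @param counts data.frame from [copy_number_table()] (or a named integer
#'   vector of per-genome counts).
#' @param taxonomy Named character vector, genome id -> taxon label.
#' @return data.frame with one row per taxon: `taxon`, `n_genomes`,
#'   `n_encoding`, `prevalence`, `mean_copies`, `sd_copies`, `max_copies`.
#' @export
taxon_profile <- function(counts, taxonomy) {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$copy_number, counts$genome_id)
  missing_tax <- setdiff(names(counts), names(taxonomy))
  if (length(missing_tax))
    stopf("no taxon label for genome(s): %s", paste(missing_tax, collapse = ", "))
  taxa <- taxonomy[names(counts)]
  rows <- lapply(sort(unique(taxa)), function(tx) {
    x <- as.numeric(counts[taxa == tx])
    enc <- x[x > 0]
    data.frame(
      taxon = tx, n_genomes = length(x), n_encoding = length(enc),
      prevalence = length(enc) / length(x),
      mean_copies = if (length(enc)) mean(enc) else NA_real_,
      sd_copies = if (length(enc) >= 2L) stats::sd(enc) else NA_real_,
      max_copies = if (length(enc)) as.integer(max(enc)) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
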