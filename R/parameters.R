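#' Pipeline parameters
#'
#' Bundles every threshold used across the pipeline into one validated
#' object, so that each stage is run with a single consistent parameter set.
#'
#' @param e_threshold Sequence-level E-value cutoff for a domain hit to
#'   count towards anchor status. Comparison is inclusive (`<=`).
#' @param required_domains Character vector of Pfam accessions that must
#'   all be present on a protein for it to be called an anchor. The default
#'   pair, Oxidored_FMN (PF00724) and Pyr_redox_2 (PF07992), defines the
#'   Fe-S flavoenzyme superfamily.
#' @param max_intergenic_gap Maximum intergenic distance in bp between
#'   consecutive same-strand genes of a cluster (inclusive). The gap between
#'   genes is `next_start - prev_end - 1` in 1-based inclusive coordinates;
#'   overlapping genes count as gap 0.
#' @param min_identity Minimum pairwise identity to a cluster centroid for
#'   greedy sequence clustering, in `[0, 1]`.
#' @param max_representatives Number of representatives retained per
#'   sequence cluster; smaller clusters keep all members.
#' @param n50_min Assembly N50 threshold in bp (inclusive) for the quality
#'   filter.
#' @param network_cutoff Maximum domain-content distance for an edge in the
#'   cluster similarity network, in `[0, 1]`.
#' @param network_weights Length-2 non-negative weights `(w_J, w_A)` for
#'   the Jaccard and adjacency terms of the cluster distance; must sum to 1.
#' @param max_gap_fraction Columns whose gap fraction exceeds this value are
#'   removed when trimming alignments.
#' @param rng_seed Integer seed used by stochastic steps (representative
#'   selection, simulation) unless one is supplied explicitly.
#'
#' @return An object of class `mgc_params` (a validated named list).
#' @examples
#' p <- mgc_params()
#' p$e_threshold
#' @export
mgc_params <- function(e_threshold = 1e-5,
                       required_domains = c("PF00724", "PF07992"),
                       max_intergenic_gap = 400L,
                       min_identity = 0.9,
                       max_representatives = 5L,
                       n50_min = 50000L,
                       network_cutoff = 0.3,
                       network_weights = c(0.5, 0.5),
                       max_gap_fraction = 0.5,
                       rng_seed = 1L) {
  if (!is.numeric(e_threshold) || length(e_threshold) != 1L || e_threshold <= 0)
    stopf("'e_threshold' must be a single positive number")
  required_domains <- unique(as.character(required_domains))
  if (length(required_domains) == 0L || any(!nzchar(required_domains)))
    stopf("'required_domains' must be a non-empty set of domain accessions")
  if (!is.numeric(max_intergenic_gap) || max_intergenic_gap < 0)
    stopf("'max_intergenic_gap' must be a non-negative number of bp")
  if (min_identity < 0 || min_identity > 1)
    stopf("'min_identity' must lie in [0, 1]")
  if (max_representatives < 1)
    stopf("'max_representatives' must be >= 1")
  if (n50_min < 0) stopf("'n50_min' must be non-negative")
  if (network_cutoff < 0 || network_cutoff > 1)
    stopf("'network_cutoff' must lie in [0, 1]")
  if (length(network_weights) != 2L || any(network_weights < 0) ||
      abs(sum(network_weights) - 1) > 1e-9)
    stopf("'network_weights' must be two non-negative weights summing to 1")
  if (max_gap_fraction < 0 || max_gap_fraction > 1)
    stopf("'max_gap_fraction' must lie in [0, 1]")
  structure(list(
    e_threshold = as.numeric(e_threshold),
    required_domains = required_domains,
    max_intergenic_gap = as.integer(max_intergenic_gap),
    min_identity = as.numeric(min_identity),
    max_representatives = as.integer(max_representatives),
    n50_min = as.integer(n50_min),
    network_cutoff = as.numeric(network_cutoff),
    network_weights = as.numeric(network_weights),
    max_gap_fraction = as.numeric(max_gap_fraction),
    rng_seed = as.integer(rng_seed)
  ), class = "mgc_params")
}

#' @export
print.mgc_params <- function(x, ...) {
  cat("MGC pipeline parameters\n")
  cat("  required domains   :", paste(x$required_domains, collapse = " + "), "\n")
  cat("  E-value threshold  : <=", format(x$e_threshold), "\n")
  cat("  max intergenic gap :", x$max_intergenic_gap, "bp\n")
  cat("  network cutoff     :", x$network_cutoff,
      sprintf("(weights J=%.2f, A=%.2f)\n", x$network_weights[1], x$network_weights[2]))
  cat("  identity / reps    :", x$min_identity, "/", x$max_representatives, "\n")
  cat("  N50 threshold      :", x$n50_min, "bp\n")
  invisible(x)
}
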