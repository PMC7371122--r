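#' Substrate-category labels
#'
#' The four major substrate categories used to profile cluster function.
#' @return Character vector of allowed category labels.
#' @export
category_labels <- function() {
  c("saccharide", "peptide/amino acid", "nucleotide", "lipid")
}

new_category_map <- function(df) {
  if (!nrow(df)) stopf("a category map must contain at least one entry")
  if (!"kind" %in% names(df)) df$kind <- "category"
  bad_kind <- setdiff(unique(df$kind), c("category", "annotation"))
  if (length(bad_kind))
    stopf("unknown kind value(s): %s (allowed: category, annotation)",
          paste(bad_kind, collapse = ", "))
  is_cat <- df$kind == "category"
  bad <- setdiff(unique(df$category[is_cat]), category_labels())
  if (length(bad))
    stopf("unknown category label(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(category_labels(), collapse = ", "))
  dup <- df$domain_acc[duplicated(df$domain_acc)]
  conflict <- unique(dup[vapply(dup, function(a)
    length(unique(df$category[df$domain_acc == a])) > 1L, logical(1))])
  if (length(conflict))
    stopf("conflicting category assignments for: %s",
          paste(conflict, collapse = ", "))
  df <- unique(df[, c("domain_acc", "category", "kind")])
  df <- df[order(df$domain_acc), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("category_map", "data.frame"))
}

#' Load a domain-to-category mapping table
#'
#' Reads a tab-delimited table with columns `domain_acc` and `category`
#' (and optionally `kind`, either `"category"` — a substrate category — or
#' `"annotation"` for functional annotations such as transporter or
#' electron-carrier domains, which are reported separately and never
#' counted as substrate categories). Duplicate accessions with conflicting
#' categories, unknown category labels, and empty maps are errors.
#'
#' @param path TSV path; a header row is expected (a two-column header-less
#'   file is also accepted).
#' @return A `category_map` data.frame.
#' @export
load_category_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  header <- grepl("domain_acc", first, fixed = TRUE)
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) {
    if (ncol(tab) < 2L) stopf("%s: expected two tab-separated columns", path)
    names(tab)[1:2] <- c("domain_acc", "category")
  }
  new_category_map(tab)
}

#' Default substrate-category map
#'
#' Contains only domain-category pairs with explicit literature support:
#' the alpha-amylase (PF00128) and starch-binding (PF16738) domains mark
#' saccharide catabolism and alanine dehydrogenase (PF01262) marks
#' peptide/amino acid catabolism. Real analyses should replace or extend
#' this map with a curated table via [load_category_map()].
#'
#' @return A `category_map`.
#' @export
default_category_map <- function() {
  new_category_map(data.frame(
    domain_acc = c("PF00128", "PF16738", "PF01262"),
    category = c("saccharide", "saccharide", "peptide/amino acid"),
    stringsAsFactors = FALSE))
}

#' Synthetic substrate-category map for simulations
#'
#' A fully synthetic map (fictitious PF9xxxx accessions, two per category)
#' covering all four substrate categories; used by the genome simulator so
#' that classifier recovery can be tested without asserting any real
#' Pfam-to-category assignment.
#'
#' @return A `category_map`.
#' @export
synthetic_category_map <- function() {
  new_category_map(data.frame(
    domain_acc = sprintf("PF97%02d%d", rep(1:4, each = 2), rep(1:2, 4)),
    category = rep(category_labels(), each = 2),
    stringsAsFactors = FALSE))
}

#' Predict substrate categories for a cluster
#'
#' The cluster's categories are the union of the categories of all mapped
#' domains it contains; unmapped domains contribute nothing, and a cluster
#' with no mapped domain gets an empty set (unknown function).
#'
#' @param cluster One-row cluster data.frame (or character vector of
#'   domain accessions).
#' @param map A `category_map`.
#' @return Sorted character vector of category labels (possibly empty).
#' @export
classify_cluster <- function(cluster, map = default_category_map()) {
  stopifnot(inherits(map, "category_map"))
  doms <- unique(domain_vector(cluster))
  cats <- map$category[map$kind == "category" & map$domain_acc %in% doms]
  sort(unique(cats))
}

#' Classify families and summarise category counts
#'
#' A family's categories are the union of its member clusters' categories
#' (multi-label: a family may carry several). The summary counts each
#' family once under every category it carries, so category counts can sum
#' to more than the number of categorized families; families with no
#' category are tallied as `unknown`. Annotation-kind map entries are
#' collected into a separate `annotations` column.
#'
#' @param families Family data.frame from [families_from_network()].
#' @param clusters Cluster data.frame covering all family members.
#' @param map A `category_map`.
#' @return `list(families = <families with categories/annotations filled>,
#'   summary = <data.frame category, n_families>)`.
#' @export
classify_families <- function(families, clusters, map = default_category_map()) {
  stopifnot(inherits(map, "category_map"))
  dom_sets <- lapply(clusters$domain_string, function(s) unique(split_ids(s)))
  names(dom_sets) <- clusters$cluster_id
  cat_list <- vector("list", nrow(families))
  ann_list <- vector("list", nrow(families))
  for (i in seq_len(nrow(families))) {
    m <- split_ids(families$member_cluster_ids[i])
    missing <- setdiff(m, names(dom_sets))
    if (length(missing))
      stopf("family %s references unknown cluster(s): %s",
            families$family_id[i], paste(missing, collapse = ", "))
    doms <- unique(unlist(dom_sets[m]))
    hit <- map$domain_acc %in% doms
    cat_list[[i]] <- sort(unique(map$category[hit & map$kind == "category"]))
    ann_list[[i]] <- sort(unique(map$category[hit & map$kind == "annotation"]))
  }
  families$categories <- vapply(cat_list, function(x) paste(x, collapse = ";"),
                                character(1))
  families$annotations <- vapply(ann_list, function(x) paste(x, collapse = ";"),
                                 character(1))
  present <- intersect(category_labels(), unique(unlist(cat_list)))
  counts <- vapply(present, function(cl)
    sum(vapply(cat_list, function(x) cl %in% x, logical(1))), integer(1))
  n_unknown <- sum(vapply(cat_list, length, integer(1)) == 0L)
  summary <- data.frame(
    category = c(present, "unknown"),
    n_families = c(as.integer(counts), n_unknown),
    stringsAsFactors = FALSE)
  list(families = families, summary = summary)
}
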