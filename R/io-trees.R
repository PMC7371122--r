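#' Read and write Newick trees
#'
#' Thin, validating wrappers around ape. Reading a tree without branch
#' lengths sets them to 0 with a warning; unbalanced parentheses or other
#' syntax problems raise a parse error. `write_newick` emits one tree per
#' file with branch lengths, so read-write round trips preserve the leaf
#' set and patristic distances (topology up to child rotation).
#'
#' @param path File path.
#' @return `read_newick` returns an ape `phylo`; `write_newick` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stopf("%s: Newick parse error (unbalanced parentheses)", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stopf("%s: Newick parse error: %s", path,
                                             conditionMessage(e)))
  if (is.null(tree)) stopf("%s: Newick parse error", path)
  if (is.null(tree$edge.length)) {
    warnf("%s: tree has no branch lengths; defaulting to 0", path)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree
}

#' @param tree An ape `phylo` object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
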