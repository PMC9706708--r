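#' Read and write Newick trees
#'
#' Thin wrappers over ape's Newick parser that enforce the package's tree
#' contract: unique leaf labels, non-negative branch lengths, and a default of
#' zero (with a warning) for branches without a stated length.
#'
#' @param path file path to a Newick tree.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_tree(tr)
}

#' @rdname read_tree
#' @param text Newick string, used instead of `path`.
#' @export
parse_tree <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree an `ape::phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname read_tree
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("branches without lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}
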