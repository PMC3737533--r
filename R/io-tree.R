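#' Read a phylogenetic tree with branch lengths from a Newick file
#'
#' Branch lengths are required on every edge (they are substitutions/site and
#' the denominator of the branch length score). Duplicate leaf names are an
#' error.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(sprintf("could not parse Newick tree in %s", path))
  if (inherits(tree, "multiPhylo")) {
    abort(sprintf("%s: expected a single tree, found %d", path, length(tree)))
  }
  validate_tree(tree, path)
}

validate_tree <- function(tree, what = "tree") {
  if (!inherits(tree, "phylo")) abort("not a phylo object")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    abort(sprintf("%s: every branch must carry a branch length", what))
  }
  if (any(tree$edge.length < 0)) {
    abort(sprintf("%s: negative branch length", what))
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(sprintf("%s: duplicate leaf name '%s'", what,
                  tree$tip.label[duplicated(tree$tip.label)][1]))
  }
  tree
}

#' Total branch length of a tree
#'
#' The sum of all branch lengths; the denominator of [compute_bls()].
#'
#' @param tree A `phylo` object.
#' @return Numeric scalar.
#' @export
total_branch_length <- function(tree) {
  validate_tree(tree)
  sum(tree$edge.length)
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
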