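#' Read a single phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the structural
#' requirements of the tip-rate machinery: the tree must be rooted, carry a
#' branch length on every edge, have non-negative edge lengths and unique tip
#' labels.
#'
#' @param path Path to a Newick file containing exactly one tree.
#' @return An object of class `phylo`.
#' @seealso [read_newick_set()] for multi-tree (posterior sample) files.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    stop("file contains ", length(tr),
         " trees; use read_newick_set() for posterior samples")
  }
  validate_phylogeny(tr, context = path)
  tr
}

#' Read a posterior sample of phylogenies from a multi-tree Newick file
#'
#' @param path Path to a Newick file with one tree per line (or any format
#'   `ape::read.tree` accepts for multiple trees).
#' @return A list of validated `phylo` objects (class `multiPhylo`).
#' @export
read_newick_set <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- c(tr) # promote singleton to multiPhylo
  for (i in seq_along(tr)) validate_phylogeny(tr[[i]], context = sprintf("%s [tree %d]", path, i))
  tr
}

#' Write one tree or a set of trees to Newick
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks that the tree is rooted, binary or multifurcating (no singleton
#' nodes), that every edge has a finite non-negative length, and that tip
#' labels are unique. Called by all readers and simulators; exported because
#' user-supplied `phylo` objects should pass through the same gate.
#'
#' @param tree A `phylo` object.
#' @param context Optional string naming the source, used in error messages.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree, context = "tree") {
  if (!inherits(tree, "phylo")) stop(context, ": not a 'phylo' object")
  if (is.null(tree$edge.length)) {
    stop(context, ": tree has no branch lengths (required)")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop(context, ": tree has missing or non-finite branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop(context, ": negative branch lengths")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop(context, ": duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  # rooted = exactly one parentless node with >= 2 daughters; a basal
  # polytomy counts as a rooted multifurcation here
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  if (length(root) != 1) stop(context, ": tree must have exactly one root")
  if (sum(tree$edge[, 1] == root) < 2) stop(context, ": root has fewer than 2 daughters")
  # every tip reachable from the root: guaranteed by a well-formed edge
  # matrix, but guard against corrupted objects
  ntot <- ape::Ntip(tree) + tree$Nnode
  seen <- unique(as.vector(tree$edge))
  if (!all(seq_len(ape::Ntip(tree)) %in% seen)) {
    stop(context, ": some tips are not connected to the root")
  }
  if (length(seen) != ntot) stop(context, ": edge matrix does not cover all nodes")
  invisible(tree)
}
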