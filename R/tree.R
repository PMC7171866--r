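#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' downstream metrics rely on: the tree must parse, be rooted, and carry
#' branch lengths (non-negative). An unrooted tree (basal polytomy) is
#' rejected unless `midpoint_root = TRUE`, in which case it is midpoint
#' rooted via [phangorn::midpoint()].
#'
#' @param path Path to a Newick file.
#' @param midpoint_root Root an unrooted tree at its midpoint instead of
#'   erroring. Default `FALSE`.
#' @param allow_missing_lengths Replace absent branch lengths with zero
#'   instead of erroring. Default `FALSE`.
#' @return An [ape::phylo] object, rooted, with branch lengths.
#' @export
read_tree <- function(path, midpoint_root = FALSE, allow_missing_lengths = FALSE) {
  if (!file.exists(path)) stop_ea(paste0("no such file: ", path))
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop_ea(paste0("unparseable Newick: ", conditionMessage(e))))
  if (is.null(tree)) stop_ea("unparseable Newick file")
  validate_tree(tree, midpoint_root = midpoint_root,
                allow_missing_lengths = allow_missing_lengths)
}

# shared validation for trees however obtained
validate_tree <- function(tree, midpoint_root = FALSE, allow_missing_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stop_ea("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop_ea("duplicate tip labels")
  if (is.null(tree$edge.length)) {
    if (!allow_missing_lengths) stop_ea("tree has no branch lengths (set allow_missing_lengths = TRUE to use zeros)")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop_ea("negative branch lengths")
  if (!ape::is.rooted(tree)) {
    if (!midpoint_root) {
      stop_ea("tree is unrooted; re-root it or call with midpoint_root = TRUE")
    }
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Pairwise cophenetic (patristic) distances
#'
#' Sum of branch lengths along the path between every pair of tips; the
#' phylogenetic distance substrate for [bmntd()], [pina()] and the
#' phylogenetic-signal correlogram.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @return A square symmetric matrix (tips x tips) with zero diagonal, in
#'   branch-length units.
#' @export
cophenetic_distances <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  # ape returns tips in tree order; enforce symmetric zero-diagonal contract
  d[cbind(seq_len(nrow(d)), seq_len(nrow(d)))] <- 0
  as_pairwise_matrix((d + t(d)) / 2, rownames(d), "dissimilarity")
}
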