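#' Bray-Curtis dissimilarity
#'
#' `d(A,B) = sum_i |x_iA - x_iB| / sum_i (x_iA + x_iB)` on counts, or on
#' within-sample relative abundances when `relative = TRUE` (equivalent when
#' all samples share the same depth, e.g. after [rarefy()]).
#'
#' @param x Samples x taxa abundance matrix; every row sum must be > 0.
#' @param relative Convert rows to relative abundances first.
#' @return A [stats::dist] with values in `[0, 1]`.
#' @export
bray_curtis <- function(x, relative = FALSE) {
  validate_counts(x, integer_only = FALSE)
  if (any(rowSums(x) <= 0)) stop_ea("zero-sum sample(s); Bray-Curtis undefined")
  if (nrow(x) < 2) stop_ea("need at least 2 samples")
  if (relative) x <- rel_abund(x)
  vegan::vegdist(x, method = "bray")
}

# relative abundance subtended by every branch: samples x edges matrix
branch_proportions <- function(x, tree) {
  check_taxa_in_tree(x, tree)
  p_tip <- matrix(0, nrow(x), length(tree$tip.label),
                  dimnames = list(rownames(x), tree$tip.label))
  p_tip[, colnames(x)] <- rel_abund(x)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  edge <- tree_po$edge
  n_tip <- length(tree$tip.label)
  # node relative abundance accumulated tips-up
  node_p <- matrix(0, nrow(x), n_tip + tree$Nnode)
  node_p[, seq_len(n_tip)] <- p_tip
  for (e in seq_len(nrow(edge))) {
    node_p[, edge[e, 1]] <- node_p[, edge[e, 1]] + node_p[, edge[e, 2]]
  }
  list(p = node_p[, edge[, 2], drop = FALSE], lengths = tree_po$edge.length)
}

#' Generalized UniFrac dissimilarity
#'
#' Chen-style generalized UniFrac with branch-weight moderation exponent
#' `alpha`:
#' `d = sum_b L_b (p_bA + p_bB)^alpha |p_bA - p_bB| / (p_bA + p_bB)` divided
#' by `sum_b L_b (p_bA + p_bB)^alpha`, over branches with
#' `p_bA + p_bB > 0`, where `p_b` is the relative abundance subtended by
#' branch `b`. `alpha = 1` recovers (normalized) weighted UniFrac;
#' `alpha = 0.5` (default) is the usual compromise that tempers the
#' dominance of abundant lineages.
#'
#' @param x Samples x taxa abundance matrix (taxa must all be tree tips).
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param alpha Moderation exponent in `[0, 1]`.
#' @return A [stats::dist] with values in `[0, 1]`.
#' @export
gunifrac <- function(x, tree, alpha = 0.5) {
  validate_counts(x, integer_only = FALSE)
  tree <- validate_tree(tree)
  if (alpha < 0 || alpha > 1) stop_ea("alpha must be in [0, 1]")
  bp <- branch_proportions(x, tree)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      pa <- bp$p[a, ]; pb <- bp$p[b, ]
      tot <- pa + pb
      use <- tot > 0
      wgt <- bp$lengths[use] * tot[use]^alpha
      d[a, b] <- d[b, a] <- sum(wgt * abs(pa[use] - pb[use]) / tot[use]) / sum(wgt)
    }
  }
  stats::as.dist(d)
}

#' Sequential beta-diversity along the cruise track
#'
#' Compares each station with its immediate predecessor in cruise order and
#' flags abrupt compositional changes (dissimilarity strictly above
#' `threshold`; the presets used for ocean surveys are 0.8 for
#' picoeukaryotes and 0.7 for prokaryotes on Bray-Curtis).
#'
#' @param dist A [stats::dist] or square dissimilarity matrix over samples.
#' @param metadata Data frame with `sample_id` and integer `cruise_order`
#'   covering every sample in `dist`.
#' @param threshold Abrupt-change threshold (strict `>`).
#' @return A tibble of class `sequential_beta` with one row per station
#'   from the second onward (in cruise order): `sample_id`, `previous_id`,
#'   `cruise_order`, `dissimilarity`, `abrupt`; `threshold` is kept as an
#'   attribute.
#' @export
sequential_beta <- function(dist, metadata, threshold = 0.8) {
  m <- as.matrix(dist)
  if (!all(c("sample_id", "cruise_order") %in% names(metadata)))
    stop_ea("metadata must contain sample_id and cruise_order")
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  if (any(is.na(meta$cruise_order))) stop_ea("cruise_order missing for some samples")
  ord <- order(meta$cruise_order)
  ids <- meta$sample_id[ord]
  dvals <- m[cbind(ids[-1], ids[-length(ids)])]
  out <- tibble::tibble(
    sample_id = ids[-1],
    previous_id = ids[-length(ids)],
    cruise_order = sort(meta$cruise_order)[-1],
    dissimilarity = unname(dvals),
    abrupt = unname(dvals) > threshold
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("sequential_beta", class(out))
  out
}
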