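#' Taxon-taxon association matrix from co-occurrence profiles
#'
#' Pairwise correlation of relative-abundance profiles across samples,
#' rescaled from `[-1, 1]` to `[0, 1]` via `a = (rho + 1) / 2`, so 1 means
#' perfect co-occurrence, 0.5 neutral association and 0 perfect avoidance.
#' The diagonal is forced to 1. Taxa with zero variance across samples have
#' undefined correlations; their associations are set to the neutral 0.5
#' (with a warning) so the taxon set stays aligned with the other metrics.
#'
#' @param x Samples x taxa abundance matrix with >= 3 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A square symmetric matrix in `[0, 1]` with unit diagonal;
#'   attribute `estimator` records the method.
#' @export
taxon_associations <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  validate_counts(x, integer_only = FALSE)
  if (nrow(x) < 3) stop_ea("need >= 3 samples to estimate associations")
  p <- rel_abund(x)
  zero_var <- apply(p, 2, function(v) stats::var(v) == 0)
  rho <- suppressWarnings(stats::cor(p, method = method))
  a <- (rho + 1) / 2
  if (any(zero_var)) {
    rlang::warn(paste0("zero-variance taxa set to neutral association 0.5: ",
                       paste(colnames(x)[zero_var], collapse = ", ")))
    a[zero_var, ] <- 0.5
    a[, zero_var] <- 0.5
  }
  diag(a) <- 1
  a <- (a + t(a)) / 2
  attr(a, "estimator") <- method
  a
}

# generalized-cosine similarity under a kernel: the shared core of TINA/PINA
kernel_cosine <- function(P, a) {
  G <- P %*% a %*% t(P) # G[A,B] = sum_ij p_iA p_jB a_ij
  selfsim <- diag(G)
  if (any(selfsim <= 0)) {
    stop_ea(paste0("zero self-similarity for sample(s): ",
                   paste(rownames(P)[selfsim <= 0], collapse = ", ")))
  }
  s <- G / sqrt(outer(selfsim, selfsim))
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Taxa interaction-adjusted community similarity (TINA)
#'
#' Generalized cosine of the two samples' abundance vectors under a
#' taxon-association kernel:
#' `s(A,B) = sum_ij p_iA p_jB a_ij / sqrt(sum_ij p_iA p_jA a_ij * sum_ij p_iB p_jB a_ij)`.
#' Identical samples (or perfectly associated taxa) give 1; disjoint
#' samples with neutral cross-associations give values near 0.5; complete
#' avoidance gives values near 0. The dissimilarity used downstream is
#' `1 - TINA` (see [as_dissimilarity()]).
#'
#' @param x Samples x taxa abundance matrix.
#' @param assoc Association matrix from [taxon_associations()] (or any
#'   symmetric kernel with unit diagonal covering the table's taxa).
#' @param weighted Use relative abundances (`TINA_w`, default) or
#'   presence-normalized indicators (unweighted).
#' @return Square symmetric similarity matrix with unit diagonal,
#'   `kind = "similarity"`.
#' @export
tina <- function(x, assoc, weighted = TRUE) {
  validate_counts(x, integer_only = FALSE)
  if (!all(colnames(x) %in% colnames(assoc)))
    stop_ea("association matrix must cover every taxon in the table")
  a <- assoc[colnames(x), colnames(x), drop = FALSE]
  P <- bmntd_weights(x, weighted)
  s <- kernel_cosine(P, a)
  out <- as_pairwise_matrix(s, rownames(x), "similarity")
  attr(out, "estimator") <- attr(assoc, "estimator") %||% "custom"
  out
}

#' Phylogenetic interaction-adjusted community similarity (PINA)
#'
#' Same generalized-cosine form as [tina()], with the association kernel
#' replaced by phylogenetic similarity `1 - delta_ij / max(delta)` from the
#' cophenetic distances of the tree.
#'
#' @param x Samples x taxa abundance matrix; taxa must all be tree tips.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param weighted Abundance-weighted (`PINA_w`, default) or unweighted.
#' @return Square symmetric similarity matrix with unit diagonal.
#' @export
pina <- function(x, tree, weighted = TRUE) {
  tree <- validate_tree(tree)
  check_taxa_in_tree(x, tree)
  D <- cophenetic_distances(tree)[colnames(x), colnames(x), drop = FALSE]
  dmax <- max(D)
  if (dmax == 0) stop_ea("degenerate tree: all cophenetic distances are zero")
  a <- 1 - D / dmax
  attr(a, "estimator") <- "phylogenetic"
  tina(x, a, weighted = weighted)
}

#' Convert a similarity matrix to a dissimilarity
#'
#' `1 - s`, as used for interaction-adjusted beta-diversity (`1 - TINA`).
#'
#' @param sim Square similarity matrix with unit diagonal.
#' @return A [stats::dist].
#' @export
as_dissimilarity <- function(sim) {
  if (!identical(attr(sim, "kind"), "similarity"))
    stop_ea("input must be a similarity matrix")
  stats::as.dist(1 - sim)
}
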