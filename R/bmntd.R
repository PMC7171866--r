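# Core of the phylogenetic-turnover machinery.
#
# bmntd_core() is shared by the observed statistic and every null
# randomization: given P (samples x taxa relative abundances, or
# 1/richness weights for the unweighted variant) and D (taxa x taxa
# cophenetic distances) it returns the full pairwise matrix
#   bMNTD(k,m) = 0.5 * [ sum_i f_ik min_{j in m} D_ij
#                      + sum_j f_jm min_{i in k} D_ji ].
# The nearest-taxon search runs over the other community's *present* taxa,
# including a shared taxon itself (distance 0).

bmntd_core <- function(P, D) {
  n <- nrow(P)
  t_idx <- lapply(seq_len(n), function(k) which(P[k, ] > 0))
  # M[i, m] = min distance from taxon i to any taxon present in sample m
  M <- vapply(seq_len(n), function(m) {
    idx <- t_idx[[m]]
    if (length(idx) == 1) D[, idx] else do.call(pmin, lapply(idx, function(j) D[, j]))
  }, numeric(ncol(P)))
  A <- P %*% M # A[k, m] = sum_i f_ik * min_j-in-m D_ij
  0.5 * (A + t(A))
}

# weights matrix for bmntd: relative abundances or 1/richness indicators
bmntd_weights <- function(x, weighted) {
  if (any(rowSums(x > 0) == 0)) stop_ea("empty community (no taxa present)")
  if (weighted) rel_abund(x) else {
    inc <- (x > 0) * 1
    sweep(inc, 1, rowSums(inc), "/")
  }
}

#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For each pair of communities, the abundance-weighted mean of the
#' phylogenetic distance from every taxon in one community to its
#' evolutionary closest taxon in the other, averaged over both directions.
#' Small values mean the two communities are built from phylogenetically
#' close taxa. The unweighted variant replaces relative abundances by
#' `1/richness`.
#'
#' @param x Samples x taxa abundance matrix; taxa must all be tree tips.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param weighted Abundance-weighted (default) or incidence-based.
#' @return A [stats::dist] of beta-MNTD values in branch-length units.
#' @export
bmntd <- function(x, tree, weighted = TRUE) {
  validate_counts(x, integer_only = FALSE)
  tree <- validate_tree(tree)
  check_taxa_in_tree(x, tree)
  D <- cophenetic_distances(tree)[colnames(x), colnames(x), drop = FALSE]
  P <- bmntd_weights(x, weighted)
  stats::as.dist(bmntd_core(P, D))
}

#' Beta nearest taxon index (beta-NTI)
#'
#' Standardized effect size of [bmntd()] against a null model that shuffles
#' taxon identities (with their abundances) across the tips of the
#' phylogeny: `bNTI = (bMNTD_obs - mean_null) / sd_null`. `|bNTI| > 2` is
#' conventionally read as a significant departure from stochastic
#' phylogenetic turnover — positive values indicate heterogeneous
#' selection, negative values homogeneous selection.
#'
#' One tip shuffle per randomization is reused for every community pair
#' (matrix-level null, the behaviour of the standard reference scripts);
#' `null = "exhaustive"` replaces sampling with all `n_taxa!` relabelings
#' (small taxon sets only).
#'
#' @param x Samples x taxa abundance matrix.
#' @param tree Rooted [ape::phylo]; tips must cover the table's taxa.
#' @param n_null Number of randomizations (default 999).
#' @param seed Integer seed.
#' @param weighted Abundance-weighted beta-MNTD (default).
#' @param null `"sample"` (Monte-Carlo, default) or `"exhaustive"`.
#' @return A list of class `bnti_result`: square matrices `bmntd_obs`,
#'   `null_mean`, `null_sd`, `bnti`; entries with zero null sd are `NA`
#'   (with a warning). Pair order matches `rownames(x)`.
#' @export
bnti <- function(x, tree, n_null = 999, seed = 1, weighted = TRUE,
                 null = c("sample", "exhaustive")) {
  null <- match.arg(null)
  validate_counts(x, integer_only = FALSE)
  tree <- validate_tree(tree)
  check_taxa_in_tree(x, tree)
  if (n_null < 1) stop_ea("n_null must be >= 1")
  taxa <- colnames(x)
  D <- cophenetic_distances(tree)[taxa, taxa, drop = FALSE]
  P <- bmntd_weights(x, weighted)
  obs <- bmntd_core(P, D)
  n_taxa <- length(taxa)
  if (null == "exhaustive") {
    if (n_taxa > 8) stop_ea("exhaustive null only supported for <= 8 taxa")
    perms <- all_permutations(n_taxa)
  } else {
    set.seed(as.integer(seed))
    perms <- t(vapply(seq_len(n_null), function(i) sample.int(n_taxa),
                      integer(n_taxa)))
  }
  # shuffling taxa across tips == permuting the columns of P against fixed D
  s1 <- matrix(0, nrow(x), nrow(x))
  s2 <- matrix(0, nrow(x), nrow(x))
  for (r in seq_len(nrow(perms))) {
    bn <- bmntd_core(P[, perms[r, ], drop = FALSE], D)
    s1 <- s1 + bn
    s2 <- s2 + bn^2
  }
  nr <- nrow(perms)
  mu <- s1 / nr
  va <- pmax(s2 / nr - mu^2, 0) * nr / max(nr - 1, 1)
  sdv <- sqrt(va)
  z <- (obs - mu) / sdv
  degenerate <- sdv == 0
  diag(degenerate) <- FALSE
  if (any(degenerate)) {
    rlang::warn("null sd is zero for some pairs; their bNTI is NA")
    z[degenerate] <- NA_real_
  }
  diag(z) <- 0
  labs <- rownames(x)
  structure(list(
    bmntd_obs = as_pairwise_matrix(obs, labs, "dissimilarity"),
    null_mean = as_pairwise_matrix(mu, labs, "dissimilarity"),
    null_sd = as_pairwise_matrix(sdv, labs, "dissimilarity"),
    bnti = as_pairwise_matrix(z, labs, "dissimilarity"),
    n_null = nr, weighted = weighted, null = null
  ), class = "bnti_result")
}

#' @export
print.bnti_result <- function(x, ...) {
  v <- lower_vec(x$bnti)
  cat(sprintf("bNTI over %d pairs (%d randomizations, %s null)\n",
              length(v), x$n_null, x$null))
  cat(sprintf("  |bNTI| > 2 in %d pairs (%.1f%%); range %.2f .. %.2f\n",
              sum(abs(v) > 2, na.rm = TRUE),
              100 * mean(abs(v) > 2, na.rm = TRUE),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}
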