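#' Phylogenetic signal in habitat preferences (Mantel correlogram)
#'
#' Prerequisite check for interpreting beta-NTI: closely related taxa
#' should have more similar environmental optima than distant ones, at
#' least across short phylogenetic distances. Each taxon's niche value is
#' its abundance-weighted mean of the environmental variable over the
#' samples it occurs in; the correlogram then relates between-taxon niche
#' distance `|niche_i - niche_j|` to cophenetic distance over equal-width
#' phylogenetic distance classes, with permutation tests and progressive
#' Holm correction.
#'
#' @param x Samples x taxa abundance matrix.
#' @param env Numeric vector, one environmental value per sample (in row
#'   order of `x`), or the name of a column in `metadata`.
#' @param tree Rooted [ape::phylo] covering the table's taxa.
#' @param metadata Optional data frame with `sample_id` and the `env`
#'   column, used when `env` is a name.
#' @param n_classes Number of equal-width phylogenetic distance classes.
#' @param n_perm Permutations per class.
#' @param seed Integer seed.
#' @return A `mantel_correlogram` tibble (see [mantel_correlogram()]):
#'   `class_index`, `class_midpoint`, `n_pairs`, `mantel_r`, `p_value`,
#'   `p_corrected`.
#' @export
phylo_signal_correlogram <- function(x, env, tree, metadata = NULL,
                                     n_classes = 10, n_perm = 999, seed = 1) {
  validate_counts(x, integer_only = FALSE)
  tree <- validate_tree(tree)
  check_taxa_in_tree(x, tree)
  if (is.character(env)) {
    if (is.null(metadata)) stop_ea("metadata needed when env is a column name")
    env <- metadata[[env]][match(rownames(x), metadata$sample_id)]
  }
  if (length(env) != nrow(x) || any(is.na(env)))
    stop_ea("env must provide one non-missing value per sample")
  # abundance-weighted niche value per taxon
  wsum <- colSums(x * env)
  tot <- colSums(x)
  if (any(tot == 0)) stop_ea("taxa with zero total abundance; filter the table first")
  niche <- wsum / tot
  if (stats::var(niche) == 0) stop_ea("all taxa share one niche value; correlation undefined")
  d_niche <- stats::dist(niche)
  d_phylo <- stats::as.dist(cophenetic_distances(tree)[colnames(x), colnames(x)])
  set.seed(as.integer(seed))
  cl <- vegan::mantel.correlog(d_niche, D.geo = d_phylo, n.class = n_classes,
                               nperm = n_perm, mult = "holm", progressive = TRUE)
  correlogram_tibble(cl)
}

# convert vegan::mantel.correlog output to the package's tibble form
correlogram_tibble <- function(cl) {
  m <- as.data.frame(cl$mantel.res)
  out <- tibble::tibble(
    class_index = seq_len(nrow(m)),
    class_midpoint = m$class.index,
    n_pairs = as.integer(m$n.dist / 2), # vegan counts both matrix triangles
    mantel_r = m$Mantel.cor,
    p_value = m[["Pr(Mantel)"]],
    p_corrected = m[["Pr(corrected)"]]
  )
  class(out) <- c("mantel_correlogram", class(out))
  out
}
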