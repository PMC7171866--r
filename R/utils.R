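# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort warn
NULL

stop_ea <- function(msg, class = "ecoassembly_error") {
  rlang::abort(msg, class = class)
}

# relative abundances by sample (rows); rows must have positive sums
rel_abund <- function(x) {
  rs <- rowSums(x)
  if (any(rs <= 0)) {
    stop_ea(paste0("samples with zero total counts: ",
                   paste(rownames(x)[rs <= 0], collapse = ", ")))
  }
  sweep(x, 1, rs, "/")
}

# validate a samples x taxa count matrix
validate_counts <- function(x, integer_only = TRUE, what = "counts") {
  if (!is.matrix(x)) stop_ea(sprintf("%s must be a matrix (samples x taxa)", what))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_ea(sprintf("%s must carry sample (row) and taxon (column) names", what))
  if (anyDuplicated(rownames(x))) stop_ea("duplicate sample ids")
  if (anyDuplicated(colnames(x))) stop_ea("duplicate taxon ids")
  if (any(!is.finite(x))) stop_ea(sprintf("%s contains non-finite values", what))
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop_ea(sprintf("negative count at sample '%s', taxon '%s'",
                    rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (integer_only && any(x != round(x))) {
    bad <- which(x != round(x), arr.ind = TRUE)[1, ]
    stop_ea(sprintf("non-integer count at sample '%s', taxon '%s'",
                    rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  invisible(x)
}

# check table taxa are a subset of tree tips
check_taxa_in_tree <- function(x, tree) {
  missing <- setdiff(colnames(x), tree$tip.label)
  if (length(missing) > 0) {
    stop_ea(paste0("taxa absent from the tree: ",
                   paste(utils::head(missing, 10), collapse = ", "),
                   if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10) else ""))
  }
  invisible(TRUE)
}

# square symmetric matrix with given kind tag; used for similarity outputs
as_pairwise_matrix <- function(m, labels, kind = c("dissimilarity", "similarity")) {
  kind <- match.arg(kind)
  dimnames(m) <- list(labels, labels)
  attr(m, "kind") <- kind
  m
}

# lower-triangle vector of a square matrix / dist
lower_vec <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}

# enumerate all permutations of 1..n (small n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

# derive a reproducible child seed (< 2^31) from a master seed and an offset
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483587L
}
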