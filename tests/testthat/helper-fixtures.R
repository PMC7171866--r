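# fixtures built in code; no data files

# labelled samples x taxa count matrix
ct <- function(..., samples = NULL, taxa = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  rownames(m) <- samples %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- taxa %||% paste0("t", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random count table with guaranteed positive row sums
rand_table <- function(n_samples, n_taxa, seed = 1, depth = 100, zero_frac = 0.3) {
  set.seed(seed)
  p <- matrix(rexp(n_samples * n_taxa), n_samples, n_taxa)
  p[runif(length(p)) < zero_frac] <- 0
  p[, colSums(p) == 0] <- 1e-3 # keep every taxon observed somewhere
  m <- t(vapply(seq_len(n_samples), function(i) {
    pr <- p[i, ]
    if (all(pr == 0)) pr[1] <- 1
    stats::rmultinom(1, depth, pr)[, 1]
  }, integer(n_taxa)))
  rownames(m) <- paste0("S", seq_len(n_samples))
  colnames(m) <- paste0("t", seq_len(n_taxa))
  # ensure no empty sample
  m[rowSums(m) == 0, 1] <- 1L
  m
}

# random tree whose tips match t1..tn
rand_tree <- function(n_taxa, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}

# independent double-loop beta-MNTD (oracle; deliberately naive)
bmntd_brute <- function(x, tree, weighted = TRUE) {
  D <- ape::cophenetic.phylo(tree)[colnames(x), colnames(x)]
  n <- nrow(x)
  out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (k in seq_len(n)) for (m in seq_len(n)) {
    if (k == m) next
    ik <- which(x[k, ] > 0); im <- which(x[m, ] > 0)
    fk <- if (weighted) x[k, ik] / sum(x[k, ik]) else rep(1 / length(ik), length(ik))
    fm <- if (weighted) x[m, im] / sum(x[m, im]) else rep(1 / length(im), length(im))
    s1 <- 0
    for (i in seq_along(ik)) s1 <- s1 + fk[i] * min(D[ik[i], im])
    s2 <- 0
    for (j in seq_along(im)) s2 <- s2 + fm[j] * min(D[im[j], ik])
    out[k, m] <- 0.5 * (s1 + s2)
  }
  out
}

# independent weighted UniFrac (alpha = 1 gUniFrac) via phangorn clades
wunifrac_brute <- function(x, tree) {
  p <- sweep(x, 1, rowSums(x), "/")
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  pb <- vapply(desc, function(tips) {
    labs <- tree$tip.label[tips]
    rowSums(p[, intersect(labs, colnames(p)), drop = FALSE])
  }, numeric(nrow(x)))
  L <- tree$edge.length
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    num <- sum(L * abs(pb[a, ] - pb[b, ]))
    den <- sum(L * (pb[a, ] + pb[b, ]))
    d[a, b] <- d[b, a] <- num / den
  }
  d
}

lower_vec_test <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}

# metadata for a transect of n equally spaced equatorial stations
transect_meta <- function(n, spacing_km = 500) {
  km_per_deg <- 2 * pi * 6371 / 360
  tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    latitude = rep(0, n),
    longitude = (seq_len(n) - 1) * spacing_km / km_per_deg,
    cruise_order = seq_len(n),
    temperature = seq(15, 29, length.out = n),
    province = factor(paste0("p", cut(seq_len(n), 2, labels = FALSE)))
  )
}
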