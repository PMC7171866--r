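#' Great-circle distances between stations
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param metadata Data frame with `sample_id`, `latitude` (-90..90) and
#'   `longitude` (-180..180).
#' @return A [stats::dist] in kilometres, labelled by `sample_id`.
#' @export
haversine_distances <- function(metadata) {
  need <- c("sample_id", "latitude", "longitude")
  if (!all(need %in% names(metadata))) stop_ea("metadata must contain sample_id, latitude, longitude")
  lat <- metadata$latitude; lon <- metadata$longitude
  if (any(is.na(lat)) || any(is.na(lon))) stop_ea("missing coordinates")
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) stop_ea("coordinates out of range")
  m <- geosphere::distm(cbind(lon, lat), fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(m) <- list(metadata$sample_id, metadata$sample_id)
  stats::as.dist(m)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Pearson or Spearman) between the lower triangles, with a
#' one-sided permutation test permuting the rows/columns of `d2`. The
#' p-value follows the add-one rule, `p = (1 + #[r_perm >= r_obs]) /
#' (n_perm + 1)`, the observed configuration counting as one permutation.
#' With `permutations = "exhaustive"` all `n!` relabelings are enumerated
#' instead (small n), and `p` is the exact fraction with
#' `r_perm >= r_obs`.
#'
#' @param d1,d2 [stats::dist] objects or square matrices over the same
#'   labelled samples.
#' @param method `"pearson"` (default) or `"spearman"` (the rho-style
#'   report common for distance-decay work).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed.
#' @param permutations `"sample"` or `"exhaustive"`.
#' @return A list of class `mantel_test`: `statistic` (r), `p_value`,
#'   `method`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = 1,
                        permutations = c("sample", "exhaustive")) {
  method <- match.arg(method)
  permutations <- match.arg(permutations)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) stop_ea("distance matrices cover different samples")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  if (!identical(dim(m1), dim(m2))) stop_ea("distance matrices of different size")
  v1 <- m1[lower.tri(m1)]
  if (stats::sd(v1) == 0 || stats::sd(m2[lower.tri(m2)]) == 0)
    stop_ea("constant distance matrix; Mantel r undefined")
  r_of <- function(mm) stats::cor(v1, mm[lower.tri(mm)], method = method)
  r_obs <- r_of(m2)
  n <- nrow(m1)
  if (permutations == "exhaustive") {
    perms <- all_permutations(n)
    r_perm <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]; r_of(m2[p, p])
    }, numeric(1))
    p_val <- mean(r_perm >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    set.seed(as.integer(seed))
    r_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n); r_of(m2[p, p])
    }, numeric(1))
    p_val <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = r_obs, p_value = p_val, method = method,
                 n_perm = n_used, permutations = permutations),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$method, x$statistic, x$p_value, x$permutations, x$n_perm))
  invisible(x)
}

#' Mantel correlogram (distance decay)
#'
#' Relates a structuring distance (typically geographic km) to a
#' beta-diversity matrix over contiguous distance classes of fixed width
#' (1000 km is the convention for basin-scale ocean transects), using the
#' indicator-membership Mantel statistic per class, permutation tests and
#' progressive Holm correction.
#'
#' @param d_struct Structuring [stats::dist] (e.g. [haversine_distances()]).
#' @param d_beta Community dissimilarity [stats::dist].
#' @param class_width_km Width of each distance class, same units as
#'   `d_struct`.
#' @param n_perm Permutations per class.
#' @param seed Integer seed.
#' @param cutoff Passed to [vegan::mantel.correlog()]; `FALSE` (default)
#'   tests every class, matching transect-wide distance-decay analyses.
#' @return A `mantel_correlogram` tibble: `class_index`, `class_midpoint`,
#'   `n_pairs`, `mantel_r`, `p_value`, `p_corrected` (classes with too few
#'   pairs carry `NA`).
#' @export
mantel_correlogram <- function(d_struct, d_beta, class_width_km = 1000,
                               n_perm = 999, seed = 1, cutoff = FALSE) {
  ms <- as.matrix(d_struct); mb <- as.matrix(d_beta)
  if (!is.null(rownames(ms)) && !is.null(rownames(mb))) {
    if (!setequal(rownames(ms), rownames(mb))) stop_ea("matrices cover different samples")
    mb <- mb[rownames(ms), rownames(ms)]
  }
  breaks <- seq(0, max(ms) + class_width_km, by = class_width_km)
  vs <- ms[lower.tri(ms)]
  n_occupied <- length(unique(findInterval(vs, breaks, rightmost.closed = TRUE)))
  if (n_occupied < 2) {
    # one class holds every pair: the membership indicator is constant and
    # the normalized Mantel statistic is undefined
    rlang::warn("class width places every pair in one distance class; Mantel r undefined")
    out <- tibble::tibble(class_index = 1L, class_midpoint = class_width_km / 2,
                          n_pairs = length(vs), mantel_r = NA_real_,
                          p_value = NA_real_, p_corrected = NA_real_)
    class(out) <- c("mantel_correlogram", class(out))
    return(out)
  }
  set.seed(as.integer(seed))
  cl <- vegan::mantel.correlog(stats::as.dist(mb), D.geo = stats::as.dist(ms),
                               break.pts = breaks, cutoff = cutoff,
                               nperm = n_perm, mult = "holm", progressive = TRUE)
  correlogram_tibble(cl)
}

#' PERMANOVA (ADONIS) on a dissimilarity matrix
#'
#' McArdle-Anderson partitioning of the Gower-centered `-0.5 * D^2` matrix
#' with sequential (Type I) sums of squares in the order the terms are
#' given, pseudo-F per term and p-values by unrestricted permutation of
#' sample identities. Backed by [vegan::adonis2()].
#'
#' @param dist A [stats::dist] or square dissimilarity matrix.
#' @param metadata Data frame with `sample_id` plus the design variables.
#' @param terms Character vector of design variable names, in the order the
#'   sequential decomposition should use (order matters).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A tibble of class `permanova_result`: `term`, `df`, `sum_sq`,
#'   `r_squared`, `pseudo_f`, `p_value`, including Residual and Total rows.
#' @export
permanova <- function(dist, metadata, terms, n_perm = 999, seed = 1) {
  m <- as.matrix(dist)
  if (is.null(rownames(m))) stop_ea("dissimilarity matrix must be labelled")
  if (!all(terms %in% names(metadata))) {
    stop_ea(paste0("terms absent from metadata: ",
                   paste(setdiff(terms, names(metadata)), collapse = ", ")))
  }
  meta <- as.data.frame(metadata[match(rownames(m), metadata$sample_id), terms, drop = FALSE])
  if (any(is.na(meta))) stop_ea("missing values in design variables")
  for (v in terms) {
    if (length(unique(meta[[v]])) < 2)
      stop_ea(sprintf("design variable '%s' is constant", v))
  }
  mm <- stats::model.matrix(~., data = meta)
  if (qr(mm)$rank < ncol(mm)) {
    stop_ea(paste0("collinear design columns among: ", paste(terms, collapse = ", ")))
  }
  fml <- stats::as.formula(paste("stats::as.dist(m) ~", paste(terms, collapse = " + ")))
  set.seed(as.integer(seed))
  fit <- vegan::adonis2(fml, data = meta, permutations = n_perm, by = "terms")
  out <- tibble::tibble(
    term = rownames(fit),
    df = fit$Df,
    sum_sq = fit$SumOfSqs,
    r_squared = fit$R2,
    pseudo_f = fit$F,
    p_value = fit$`Pr(>F)`
  )
  class(out) <- c("permanova_result", class(out))
  out
}

#' Variance partitioning between environmental and geographic predictors
#'
#' Embeds the dissimilarity matrix by principal coordinates (axes with
#' positive eigenvalues, up to `n_axes`), then partitions the community
#' variance by redundancy analysis: adjusted R-squared for the
#' environment-only, geography-only and joint models give the pure
#' environmental, pure geographic, shared and unexplained fractions by
#' inclusion-exclusion. Adjusted R-squared can be (slightly) negative;
#' fractions are reported as-is.
#'
#' @param dist Community dissimilarity ([stats::dist] or matrix).
#' @param metadata Data frame with `sample_id` and the predictor columns.
#' @param env_vars,geo_vars Character vectors of predictor names (both
#'   non-empty); factors are expanded to dummies by the RDA.
#' @param n_axes Maximum PCoA axes to retain (default all positive).
#' @return A tibble of class `varpart_result`: `fraction` in
#'   `pure_env`, `pure_geo`, `shared`, `unexplained`; `adj_r_squared`.
#'   Fractions sum to 1.
#' @export
variance_partition <- function(dist, metadata, env_vars, geo_vars, n_axes = Inf) {
  if (length(env_vars) == 0 || length(geo_vars) == 0)
    stop_ea("both env_vars and geo_vars must be non-empty")
  m <- as.matrix(dist)
  meta <- as.data.frame(metadata[match(rownames(m), metadata$sample_id), , drop = FALSE])
  vars <- union(env_vars, geo_vars)
  if (any(is.na(meta[, vars]))) stop_ea("missing predictor values")
  n <- nrow(m)
  n_pred <- ncol(stats::model.matrix(~., data = meta[, vars, drop = FALSE])) - 1
  if (n_pred > n - 1) stop_ea("more predictors than samples - 1")
  pc <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  keep <- which(pc$eig > sqrt(.Machine$double.eps) * max(pc$eig))
  keep <- utils::head(keep, n_axes)
  Y <- pc$points[, keep, drop = FALSE]
  adj_r2 <- function(vv) {
    fit <- vegan::rda(stats::as.formula(paste("Y ~", paste(vv, collapse = " + "))),
                      data = meta)
    vegan::RsquareAdj(fit)$adj.r.squared
  }
  r_env <- adj_r2(env_vars)
  r_geo <- adj_r2(geo_vars)
  r_both <- adj_r2(union(env_vars, geo_vars))
  pure_env <- r_both - r_geo
  pure_geo <- r_both - r_env
  shared <- r_env + r_geo - r_both
  out <- tibble::tibble(
    fraction = c("pure_env", "pure_geo", "shared", "unexplained"),
    adj_r_squared = c(pure_env, pure_geo, shared, 1 - r_both)
  )
  class(out) <- c("varpart_result", class(out))
  out
}

#' Local contributions to beta diversity (LCBD)
#'
#' Decomposes the total community sum of squares (on Hellinger-transformed
#' abundances, column-centered) into per-sample contributions:
#' `LCBD_i = SS_i / SS_total`, summing to 1. Large values flag
#' compositionally unique communities. Significance per sample comes from
#' permuting each species' (transformed) values independently across
#' samples, one-sided on LCBD.
#'
#' @param x Samples x taxa abundance matrix.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A tibble of class `lcbd_result`: `sample_id`, `lcbd`,
#'   `p_value`; `ss_total` kept as an attribute.
#' @export
lcbd <- function(x, n_perm = 999, seed = 1) {
  validate_counts(x, integer_only = FALSE)
  if (nrow(x) < 2) stop_ea("need >= 2 samples")
  H <- sqrt(rel_abund(x))
  lcbd_of <- function(M) {
    C <- sweep(M, 2, colMeans(M))
    ss_i <- rowSums(C^2)
    list(ss_i = ss_i, ss_total = sum(ss_i))
  }
  obs <- lcbd_of(H)
  if (obs$ss_total == 0) stop_ea("all samples identical; beta diversity is zero")
  lc <- obs$ss_i / obs$ss_total
  set.seed(as.integer(seed))
  exceed <- rep(1L, nrow(x)) # add-one rule: observed counts as a permutation
  for (r in seq_len(n_perm)) {
    Hp <- apply(H, 2, sample)
    pp <- lcbd_of(Hp)
    lcp <- pp$ss_i / pp$ss_total
    exceed <- exceed + (lcp >= lc)
  }
  out <- tibble::tibble(
    sample_id = rownames(x),
    lcbd = unname(lc),
    p_value = unname(exceed / (n_perm + 1))
  )
  attr(out, "ss_total") <- obs$ss_total
  class(out) <- c("lcbd_result", class(out))
  out
}
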