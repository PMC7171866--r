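test_that("haversine distances use the 6371-km sphere", {
  meta <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         latitude = c(0, 0, 90, 0),
                         longitude = c(0, 180, 0, 0))
  d <- as.matrix(haversine_distances(meta))
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-6)   # half circumference
  expect_equal(d["a", "c"], pi * 6371 / 2, tolerance = 1e-6) # quarter
  expect_equal(d["a", "d"], 0)
  bad <- tibble::tibble(sample_id = "a", latitude = 91, longitude = 0)
  expect_error(haversine_distances(bad), "range")
  expect_error(haversine_distances(tibble::tibble(sample_id = "a", latitude = NA,
                                                  longitude = 1)), "missing")
})

test_that("Mantel test statistic and exhaustive p match enumeration", {
  set.seed(10)
  m <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  dimnames(m) <- list(paste0("S", 1:4), paste0("S", 1:4))
  expect_equal(mantel_test(m, m, n_perm = 9)$statistic, 1)
  # affine anticorrelation -> r = -1 (Pearson)
  m2 <- max(m) - m
  diag(m2) <- 0
  expect_equal(mantel_test(m, m2, n_perm = 9)$statistic, -1)
  # exhaustive p over all 4! relabelings vs independent enumeration
  set.seed(11)
  m3 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  dimnames(m3) <- dimnames(m)
  res <- mantel_test(m, m3, permutations = "exhaustive")
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  v1 <- m[lower.tri(m)]
  rs <- apply(perms, 1, function(p) {
    mp <- m3[p, p]
    cor(v1, mp[lower.tri(mp)])
  })
  expect_equal(res$p_value, mean(rs >= res$statistic - 1e-12))
  # r agrees with vegan's implementation
  skip_if_not_installed("vegan")
  expect_equal(mantel_test(m, m3, n_perm = 99)$statistic,
               vegan::mantel(as.dist(m), as.dist(m3), permutations = 99)$statistic,
               tolerance = 1e-12)
  # constant matrix -> undefined
  const <- matrix(1, 4, 4, dimnames = dimnames(m)); diag(const) <- 0
  expect_error(mantel_test(const * 0, m, n_perm = 9), "constant")
})

test_that("distance-decay correlogram recovers a monotone signal", {
  n <- 16
  meta <- transect_meta(n, spacing_km = 400)
  dg <- haversine_distances(meta)
  # beta-diversity as a saturating monotone function of distance + tiny noise
  set.seed(3)
  mg <- as.matrix(dg)
  mb <- 1 - exp(-mg / 2000) + matrix(runif(n * n, 0, 0.01), n, n)
  mb <- (mb + t(mb)) / 2
  diag(mb) <- 0
  cl <- mantel_correlogram(dg, mb, class_width_km = 1000, n_perm = 199, seed = 2)
  expect_gt(cl$mantel_r[1], 0)
  expect_lt(cl$p_corrected[1], 0.05)
  expect_equal(sum(cl$n_pairs, na.rm = TRUE), choose(n, 2))
  # every-pair-in-one-class binning leaves the statistic undefined
  expect_warning(one <- mantel_correlogram(dg, mb, class_width_km = 1e6, n_perm = 99),
                 "one distance class")
  expect_identical(nrow(one), 1L)
  expect_true(is.na(one$mantel_r))
})

test_that("PERMANOVA matches hand-computed and brute-force partitions", {
  # two groups of two, within-group d = 0, between-group d = 1 -> R2 = 1
  labs <- paste0("S", 1:4)
  d <- matrix(1, 4, 4, dimnames = list(labs, labs))
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0
  meta <- tibble::tibble(sample_id = labs, grp = factor(c("a", "a", "b", "b")))
  res <- permanova(d, meta, "grp", n_perm = 99, seed = 1)
  expect_equal(res$r_squared[res$term == "grp"], 1)
  expect_equal(sum(res$sum_sq[res$term != "Total"]),
               res$sum_sq[res$term == "Total"])
  # sequential SS vs explicit Gower-centering + projection oracle
  for (seed in 1:10) {
    set.seed(400 + seed)
    n <- 8
    pts <- matrix(rnorm(2 * n), n, 2)
    dd <- as.matrix(dist(pts))
    dimnames(dd) <- list(paste0("S", 1:n), paste0("S", 1:n))
    md <- tibble::tibble(sample_id = paste0("S", 1:n),
                         v1 = rnorm(n), v2 = factor(rep(c("x", "y"), n / 2)))
    got <- permanova(dd, md, c("v1", "v2"), n_perm = 19, seed = 2)
    # oracle: G = centered -D^2/2; SS by sequential projection
    J <- diag(n) - matrix(1 / n, n, n)
    G <- -0.5 * J %*% dd^2 %*% J
    ss_total <- sum(diag(G))
    hat <- function(X) X %*% solve(crossprod(X)) %*% t(X)
    X1 <- model.matrix(~v1, md)
    X12 <- model.matrix(~v1 + v2, md)
    ss1 <- sum(diag(hat(X1) %*% G)) - 0 # intercept-only hat leaves 0 after centering
    ss12 <- sum(diag(hat(X12) %*% G))
    expect_equal(got$sum_sq[got$term == "v1"], ss1, tolerance = 1e-10)
    expect_equal(got$sum_sq[got$term == "v2"], ss12 - ss1, tolerance = 1e-10)
    expect_equal(got$sum_sq[got$term == "Total"], ss_total, tolerance = 1e-10)
    expect_equal(sum(got$r_squared[got$term != "Total"]), 1, tolerance = 1e-10)
  }
  # degenerate designs
  meta1 <- tibble::tibble(sample_id = labs, grp = factor(rep("a", 4)))
  expect_error(permanova(d, meta1, "grp"), "constant")
  meta2 <- tibble::tibble(sample_id = labs, a = 1:4, b = 2 * (1:4))
  expect_error(permanova(d, meta2, c("a", "b")), "collinear")
})

test_that("variance partitioning fractions obey inclusion-exclusion", {
  set.seed(17)
  n <- 30
  env <- rnorm(n)
  geo <- rnorm(n)
  y <- cbind(env + rnorm(n, 0, .5), geo + rnorm(n, 0, .5), rnorm(n))
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("S", 1:n), paste0("S", 1:n))
  meta <- tibble::tibble(sample_id = paste0("S", 1:n), env = env, geo = geo,
                         noise1 = rnorm(n), noise2 = rnorm(n))
  vp <- variance_partition(d, meta, "env", "geo")
  expect_equal(sum(vp$adj_r_squared), 1, tolerance = 1e-9)
  expect_gt(vp$adj_r_squared[vp$fraction == "pure_env"], 0)
  # identical predictor sets -> pure fractions exactly zero
  vp_same <- variance_partition(d, meta, "env", "env")
  expect_equal(vp_same$adj_r_squared[vp_same$fraction %in% c("pure_env", "pure_geo")],
               c(0, 0), tolerance = 1e-12)
  # pure-noise predictors -> explained fractions near zero
  vp_noise <- variance_partition(d, meta, "noise1", "noise2")
  expect_lt(max(abs(vp_noise$adj_r_squared[1:3])), 0.1)
  expect_error(variance_partition(d, meta, character(0), "geo"), "non-empty")
})

test_that("LCBD decomposes total beta diversity into per-sample shares", {
  # exchangeable single-taxon samples -> exactly 1/n each
  x <- diag(5L) * 7L
  dimnames(x) <- list(paste0("S", 1:5), paste0("t", 1:5))
  res <- lcbd(x, n_perm = 49, seed = 1)
  expect_equal(res$lcbd, rep(1 / 5, 5))
  expect_equal(sum(res$lcbd), 1, tolerance = 1e-9)
  # any table: shares sum to 1
  big <- rand_table(8, 20, seed = 55, depth = 80)
  r2 <- lcbd(big, n_perm = 49, seed = 2)
  expect_equal(sum(r2$lcbd), 1, tolerance = 1e-9)
  expect_gt(attr(r2, "ss_total"), 0)
  # an outlier community takes the largest share and is detected
  base <- matrix(rep(c(30L, 30L, 30L, 5L, 5L), 6), 6, 5, byrow = TRUE)
  base[6, ] <- c(0L, 0L, 0L, 50L, 50L)
  dimnames(base) <- list(paste0("S", 1:6), paste0("t", 1:5))
  r3 <- lcbd(base, n_perm = 199, seed = 3)
  expect_identical(r3$sample_id[which.max(r3$lcbd)], "S6")
  expect_lt(r3$p_value[6], 0.05)
  # identical samples -> zero beta diversity
  same <- ct(c(1L, 2L), c(1L, 2L))
  expect_error(lcbd(same), "identical")
})
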