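test_that("pure-birth trees are ultrametric, unit depth and seed-stable", {
  tr <- simulate_tree(2, seed = 5)
  D <- cophenetic_distances(tr)
  expect_equal(D["t1", "t2"], 2) # single cherry at unit depth
  tr64 <- simulate_tree(64, seed = 9)
  expect_identical(length(tr64$tip.label), 64L)
  depths <- ape::node.depth.edgelength(tr64)[1:64]
  expect_true(max(depths) - min(depths) < 1e-9)
  expect_equal(max(depths), 1)
  expect_identical(ape::write.tree(simulate_tree(20, seed = 3)),
                   ape::write.tree(simulate_tree(20, seed = 3)))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("Brownian niche evolution has the analytic variance and signal", {
  tr <- simulate_tree(12, seed = 2)
  # sigma = 0 -> all tips at the root value
  expect_equal(unname(evolve_niche(tr, sigma = 0, root_value = 3.5, seed = 1)),
               rep(3.5, 12))
  # tip variance across replicates = sigma^2 * depth (= 1 on unit-depth trees)
  reps <- vapply(1:600, function(s) evolve_niche(tr, sigma = 1, seed = s)[["t1"]],
                 numeric(1))
  expect_equal(var(reps), 1, tolerance = 0.2)
  # trait distance correlates positively with phylogenetic distance
  cors <- vapply(1:25, function(s) {
    trr <- simulate_tree(30, seed = 700 + s)
    mu <- evolve_niche(trr, sigma = 1, seed = 800 + s)
    dmu <- as.matrix(dist(mu))
    dph <- cophenetic_distances(trr)[names(mu), names(mu)]
    cor(dmu[lower.tri(dmu)], dph[lower.tri(dph)])
  }, numeric(1))
  expect_gt(median(cors), 0)
})

test_that("community assembly is deterministic, conserves J and obeys the pool", {
  cfg <- simulation_config(n_taxa = 60, n_stations = 10, J = 2000, seed = 11)
  sim1 <- simulate_metacommunity(cfg)
  sim2 <- simulate_metacommunity(cfg)
  expect_identical(sim1$counts, sim2$counts)
  expect_equal(unname(rowSums(sim1$counts)), rep(2000, 10))
  expect_identical(nrow(sim1$metadata), 10L)
  expect_identical(sim1$metadata$cruise_order, 1:10)
  # neutral well-mixed stations converge on the pool as J grows (1/sqrt(J) law)
  dev_at <- function(J, seed) {
    s <- simulate_metacommunity(simulation_config(n_taxa = 40, n_stations = 6,
                                                  J = J, s = 0, lambda = Inf,
                                                  pool = "uniform", seed = seed))
    p <- sweep(s$counts, 1, rowSums(s$counts), "/")
    mean(abs(sweep(p, 2, s$truth$pool, "-")))
  }
  d_small <- mean(vapply(1:5, function(s) dev_at(400, s), numeric(1)))
  d_big <- mean(vapply(1:5, function(s) dev_at(40000, s), numeric(1)))
  expect_lt(d_big, d_small / 5) # expected ratio 1/10; allow Monte-Carlo slack
})

test_that("strong selection on a step environment sorts communities by step", {
  cfg <- simulation_config(n_taxa = 120, n_stations = 12, J = 5000, s = 8,
                           tau = 0.4, lambda = Inf, env_gradient = "step",
                           env_range = c(-1.5, 1.5), seed = 21)
  sim <- simulate_metacommunity(cfg)
  bc <- as.matrix(bray_curtis(sim$counts[, colSums(sim$counts) > 0]))
  step <- sim$metadata$temperature > 0
  same <- bc[outer(step, step, "==") & upper.tri(bc)]
  diff <- bc[outer(step, step, "!=") & upper.tri(bc)]
  expect_lt(mean(same), mean(diff))
})

test_that("dispersal limitation raises between-station turnover", {
  mk <- function(lambda, seed) {
    simulate_metacommunity(simulation_config(n_taxa = 100, n_stations = 10,
                                             J = 3000, s = 0, lambda = lambda,
                                             seed = seed))
  }
  mean_bc <- function(sim) mean(lower_vec_test(bray_curtis(sim$counts[, colSums(sim$counts) > 0])))
  limited <- mean(vapply(1:3, function(s) mean_bc(mk(400, s)), numeric(1)))
  mixed <- mean(vapply(1:3, function(s) mean_bc(mk(Inf, s)), numeric(1)))
  expect_gt(limited, mixed)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(n_stations = 1), ">= 2")
  expect_error(simulation_config(lambda = 0), "lambda")
  expect_error(simulation_config(tau = 0), "tau")
  # all-zero weights at a station: niche far outside every taxon's reach
  tr <- simulate_tree(5, seed = 1)
  truth <- list(mu = setNames(rep(100, 5), tr$tip.label),
                source_station = rep(1L, 5), pool = rep(0.2, 5),
                env = rep(0, 4), lat = rep(0, 4), lon = 1:4)
  cfg <- simulation_config(n_taxa = 5, n_stations = 4, s = 50, tau = 0.1, seed = 2)
  expect_error(assemble_communities(tr, truth, cfg), "station")
})
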