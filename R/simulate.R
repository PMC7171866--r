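#' Configuration for the synthetic metacommunity generator
#'
#' Bundles every knob of the generative model: a pure-birth phylogeny,
#' Brownian-motion niche evolution on it (guaranteeing phylogenetic signal),
#' stations laid along a 1-D transect with an environmental gradient,
#' Gaussian environmental filtering of tunable strength, exponentially
#' distance-decaying immigration from per-taxon source stations, and one
#' multinomial draw of `J` individuals per station (ecological drift as
#' sampling noise).
#'
#' At station `k` the sampling weight of taxon `i` is
#' `m_i(k) * w_i(E_k)^s` with `w_i(E) = exp(-(E - mu_i)^2 / (2 tau^2))`,
#' `m_i(k) = pool_i * exp(-d(k, src_i) / lambda)`, `mu_i` the Brownian niche
#' optimum and `src_i` the taxon's source station. `s = 0` switches
#' selection off; `lambda = Inf` makes immigration spatially uniform
#' (well-mixed pool).
#'
#' @param n_taxa Number of tips/taxa (>= 2).
#' @param n_stations Number of stations (>= 2).
#' @param birth_rate Speciation rate of the pure-birth tree (tree depth is
#'   rescaled to 1, so this only shapes topology/branching times).
#' @param sigma_bm Brownian trait rate, trait units^2 per unit branch length.
#' @param tau Niche breadth, environment units.
#' @param s Selection strength exponent (>= 0; 0 = neutral).
#' @param lambda Dispersal decay length in km (> 0, or `Inf` for unlimited).
#' @param J Local community size, individuals per station.
#' @param immigration_m Immigration (pool-coupling) probability `m` of the
#'   Sloan neutral community model, in `(0, 1]`. Station compositions are
#'   drawn from a Dirichlet distribution with concentration
#'   `I = m J / (1 - m)` around the deterministic expectation before the
#'   multinomial census, so small `m` means strong ecological drift
#'   (independent local fluctuation around the pool) and `m = 1` disables
#'   drift beyond the census noise (pure multinomial).
#' @param station_spacing_km Spacing of the equally spaced 1-D transect.
#' @param env_gradient `"linear"`, `"step"` or `"constant"` environmental
#'   layout along the transect.
#' @param env_range Numeric length-2: environment value at the two transect
#'   ends (for `"step"`, the two plateau values).
#' @param step_fraction For `env_gradient = "step"`: fraction of stations
#'   (from the transect start) on the first plateau. Default 0.5. Values
#'   away from 0.5 create a dominant habitat plus a minority contrasting
#'   habitat — the design under which homogeneous selection among the
#'   dominant-habitat pairs is statistically identifiable (the regional
#'   pool must span more environmental variation than the compared pairs).
#' @param env_noise_sd Gaussian noise sd added to the station environment.
#' @param pool `"logseries"` (Fisher log-series metacommunity pool, many
#'   rare taxa — the rank-abundance shape of real ocean surveys) or
#'   `"uniform"`.
#' @param logseries_theta Log-series shape parameter (closer to 1 = steeper).
#' @param seed Master seed for the whole simulation.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 300, n_stations = 20, birth_rate = 1,
                              sigma_bm = 1, tau = 0.5, s = 0, lambda = Inf,
                              J = 10000, immigration_m = 0.01,
                              station_spacing_km = 500,
                              env_gradient = c("linear", "step", "constant"),
                              env_range = c(-2, 2), step_fraction = 0.5,
                              env_noise_sd = 0,
                              pool = c("logseries", "uniform"),
                              logseries_theta = 0.98, seed = 1) {
  env_gradient <- match.arg(env_gradient)
  pool <- match.arg(pool)
  if (n_taxa < 2) stop_ea("n_taxa must be >= 2")
  if (n_stations < 2) stop_ea("n_stations must be >= 2")
  if (sigma_bm < 0 || s < 0 || birth_rate <= 0) stop_ea("rates must be non-negative")
  if (tau <= 0) stop_ea("tau must be > 0")
  if (!(lambda > 0)) stop_ea("lambda must be > 0 (possibly Inf)")
  if (J < 1) stop_ea("J must be >= 1")
  if (immigration_m <= 0 || immigration_m > 1) stop_ea("immigration_m must be in (0, 1]")
  structure(list(
    n_taxa = as.integer(n_taxa), n_stations = as.integer(n_stations),
    birth_rate = birth_rate, sigma_bm = sigma_bm, tau = tau, s = s,
    lambda = lambda, J = as.integer(J), immigration_m = immigration_m,
    station_spacing_km = station_spacing_km, env_gradient = env_gradient,
    env_range = env_range, step_fraction = step_fraction,
    env_noise_sd = env_noise_sd, pool = pool,
    logseries_theta = logseries_theta, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Preset configurations for the canonical assembly regimes
#'
#' Returns a [simulation_config()] whose parameters place the metacommunity
#' in one of the textbook assembly regimes, used for parameter-recovery
#' validation: `"drift"` (no selection, unlimited dispersal),
#' `"heterogeneous_selection"` (strong filtering on a steep gradient),
#' `"homogeneous_selection"` (filtering toward one shared optimum across a
#' dominant habitat, with a small contrasting habitat anchoring the
#' regional pool — without that contrast the null model is conditioned on
#' an already-filtered pool and homogeneous selection is unidentifiable)
#' and `"dispersal_limitation"` (neutral, short dispersal decay length).
#'
#' @param regime One of the four regime names.
#' @param seed Master seed.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config` with attribute `regime`.
#' @export
regime_config <- function(regime = c("drift", "heterogeneous_selection",
                                     "homogeneous_selection", "dispersal_limitation"),
                          seed = 1, ...) {
  regime <- match.arg(regime)
  args <- switch(regime,
    drift = list(s = 0, lambda = Inf),
    heterogeneous_selection = list(s = 6, tau = 0.5, lambda = Inf,
                                   env_gradient = "linear", env_range = c(-2, 2)),
    homogeneous_selection = list(s = 2, tau = 0.7, lambda = Inf,
                                 immigration_m = 0.001, pool = "uniform",
                                 env_gradient = "step", env_range = c(-1.5, 1.5),
                                 step_fraction = 0.15),
    dispersal_limitation = list(s = 0, lambda = 500)
  )
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  cfg <- do.call(simulation_config, args)
  attr(cfg, "regime") <- regime
  cfg
}

#' Simulate a rooted ultrametric pure-birth tree
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth_rate Speciation rate.
#' @return A rooted ultrametric [ape::phylo] with `n_taxa` tips, total depth
#'   rescaled to 1 and tips labelled `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, seed = 1, birth_rate = 1) {
  if (n_taxa < 2) stop_ea("n_taxa must be >= 2")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

#' Evolve niche optima by Brownian motion along a tree
#'
#' Each child node's trait is its parent's value plus a Gaussian increment
#' with variance `sigma^2 * branch_length`, so on an ultrametric tree of
#' depth `D` tip values are marginally `Normal(root_value, sigma^2 * D)` and
#' trait differences track phylogenetic distance — the phylogenetic signal
#' the downstream null models require.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param sigma Brownian rate (trait sd per sqrt unit branch length), >= 0.
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of niche optima, one per tip.
#' @export
evolve_niche <- function(tree, sigma = 1, root_value = 0, seed = 1) {
  tree <- validate_tree(tree)
  if (sigma < 0) stop_ea("sigma must be >= 0")
  set.seed(as.integer(seed))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  val <- rep(NA_real_, n_node)
  root <- n_tip + 1L
  val[root] <- root_value
  # preorder: parents before children
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    val[edges[e, 2]] <- val[edges[e, 1]] + stats::rnorm(1, 0, sigma * sqrt(lens[e]))
  }
  stats::setNames(val[seq_len(n_tip)], tree$tip.label)
}

# station coordinates and environment for a 1-D equatorial transect
station_layout <- function(config) {
  n <- config$n_stations
  km_per_deg <- 2 * pi * 6371 / 360
  lon <- (seq_len(n) - 1) * config$station_spacing_km / km_per_deg
  env0 <- switch(config$env_gradient,
    linear = seq(config$env_range[1], config$env_range[2], length.out = n),
    step = ifelse(seq_len(n) <= round((config$step_fraction %||% 0.5) * n),
                  config$env_range[1], config$env_range[2]),
    constant = rep(config$env_range[1], n)
  )
  list(lat = rep(0, n), lon = lon, env0 = env0)
}

#' Assemble station communities under selection, dispersal and drift
#'
#' Draws one multinomial community of `config$J` individuals per station
#' with taxon weights `m_i(k) * w_i(E_k)^s` (see [simulation_config()] for
#' the model). Ground truth (niche optima, source stations, environments)
#' must come from [simulate_metacommunity()] or be supplied as the `truth`
#' list here.
#'
#' @param tree The taxon phylogeny (tips = taxa).
#' @param truth List with `mu` (named niche optima), `source_station`
#'   (integer station index per taxon), `pool` (metacommunity relative
#'   abundances), `env` (station environments), `lat`, `lon`.
#' @param config A [simulation_config()].
#' @return List with `counts` (stations x taxa integer matrix, rows sum to
#'   `J`) and `metadata` (tibble: sample_id, latitude, longitude,
#'   cruise_order, temperature, fluorescence, salinity, basin, province).
#' @export
assemble_communities <- function(tree, truth, config) {
  n <- config$n_stations
  taxa <- tree$tip.label
  if (!all(taxa %in% names(truth$mu))) stop_ea("truth$mu must cover every tip")
  mu <- truth$mu[taxa]
  set.seed(child_seed(config$seed, 3L))
  # station geometry (1-D transect => distances from spacing)
  station_km <- (seq_len(n) - 1) * config$station_spacing_km
  env <- truth$env
  # immigration weights
  if (is.infinite(config$lambda)) {
    m <- matrix(rep(truth$pool, each = n), nrow = n)
  } else {
    d_src <- abs(outer(station_km, station_km[truth$source_station], "-"))
    m <- sweep(exp(-d_src / config$lambda), 2, truth$pool, "*")
  }
  # Gaussian fitness kernel, exponent s (s = 0 -> neutral, incl. 0^0 = 1)
  w <- exp(-(outer(env, mu, "-"))^2 / (2 * config$tau^2))
  weights <- m * w^config$s
  counts <- matrix(0L, n, length(taxa),
                   dimnames = list(sprintf("S%02d", seq_len(n)), taxa))
  m_im <- config$immigration_m %||% 1
  for (k in seq_len(n)) {
    wk <- weights[k, ]
    if (!any(wk > 0)) stop_ea(sprintf("all taxon weights zero at station %d (tau too small?)", k))
    pk <- wk / sum(wk)
    if (m_im < 1) {
      # Sloan neutral-model drift: local composition ~ Dirichlet(I * p)
      conc <- m_im * config$J / (1 - m_im)
      g <- stats::rgamma(length(pk), shape = conc * pk)
      if (sum(g) == 0) g[which.max(pk)] <- 1
      pk <- g / sum(g)
    }
    counts[k, ] <- stats::rmultinom(1, config$J, pk)[, 1]
  }
  metadata <- tibble::tibble(
    sample_id = rownames(counts),
    latitude = truth$lat,
    longitude = truth$lon,
    cruise_order = seq_len(n),
    temperature = env,
    fluorescence = stats::rnorm(n, 1, 0.2),
    salinity = stats::rnorm(n, 35, 0.3),
    basin = factor(ifelse(seq_len(n) <= n / 2, "basin_A", "basin_B")),
    province = factor(paste0("prov_", cut(seq_len(n), 4, labels = FALSE)))
  )
  list(counts = counts, metadata = metadata)
}

#' Simulate a full synthetic metacommunity with known ground truth
#'
#' End-to-end generator: pure-birth tree, Brownian niche optima, log-series
#' (or uniform) metacommunity pool, per-taxon source stations, station
#' environments along the transect, then multinomial assembly via
#' [assemble_communities()]. Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()] (or [regime_config()]).
#' @return A list of class `metacommunity_sim`: `counts` (stations x taxa),
#'   `tree`, `metadata` (tibble), `truth` (tibble: taxon, mu,
#'   source_station, pool), `config`.
#' @export
simulate_metacommunity <- function(config) {
  if (!inherits(config, "simulation_config")) stop_ea("config must be a simulation_config")
  tree <- simulate_tree(config$n_taxa, seed = child_seed(config$seed, 1L),
                        birth_rate = config$birth_rate)
  mu <- evolve_niche(tree, sigma = config$sigma_bm, root_value = 0,
                     seed = child_seed(config$seed, 2L))
  set.seed(child_seed(config$seed, 4L))
  pool <- switch(config$pool,
    logseries = {
      p <- config$logseries_theta^seq_len(config$n_taxa) / seq_len(config$n_taxa)
      sample(p / sum(p)) # random assignment of ranks to taxa
    },
    uniform = rep(1 / config$n_taxa, config$n_taxa)
  )
  source_station <- sample.int(config$n_stations, config$n_taxa, replace = TRUE)
  layout <- station_layout(config)
  env <- layout$env0 + stats::rnorm(config$n_stations, 0, config$env_noise_sd)
  truth <- list(mu = mu, source_station = source_station, pool = pool,
                env = env, lat = layout$lat, lon = layout$lon)
  asm <- assemble_communities(tree, truth, config)
  structure(list(
    counts = asm$counts, tree = tree, metadata = asm$metadata,
    truth = tibble::tibble(taxon = tree$tip.label, mu = unname(mu),
                           source_station = source_station, pool = pool),
    config = config
  ), class = "metacommunity_sim")
}

#' @export
print.metacommunity_sim <- function(x, ...) {
  cat(sprintf("Synthetic metacommunity: %d stations x %d taxa, J = %d\n",
              nrow(x$counts), ncol(x$counts), x$config$J))
  cat(sprintf("  selection s = %g (tau = %g), dispersal lambda = %g km, pool = %s\n",
              x$config$s, x$config$tau, x$config$lambda, x$config$pool))
  if (!is.null(attr(x$config, "regime")))
    cat(sprintf("  regime: %s\n", attr(x$config, "regime")))
  invisible(x)
}
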