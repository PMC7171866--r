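# ecoassembly

Quantifying **selection, dispersal and ecological drift** in microbial
metacommunities from OTU/ASV count tables and a phylogeny.

Surveys of ocean (and other) microbiotas routinely ask *which ecological
processes structure these communities*: is turnover between stations driven
by environmental filtering, by limits on organism movement, or by chance?
`ecoassembly` is aimed at microbial ecologists who have a taxa × samples
count table, a rooted phylogeny of the taxa and per-station metadata, and
want the full null-model inference chain plus the spatial statistics that
corroborate it — with a seeded synthetic metacommunity generator to
validate every step against known ground truth.

## The method in brief

For every pair of communities *k*, *m*:

1. **Phylogenetic turnover** — abundance-weighted β mean nearest taxon
   distance,
   βMNTD(k,m) = ½ [ Σᵢ f_ik · min_j Δ_ij + Σⱼ f_jm · min_i Δ_ji ],
   standardized against 999 tip-shuffle randomizations into
   βNTI = (βMNTD_obs − μ_null)/σ_null.
   βNTI > +2 → **heterogeneous selection**; βNTI < −2 → **homogeneous
   selection**. (Interpretable only when habitat preference carries
   phylogenetic signal — checked by `phylo_signal_correlogram()`.)
2. **Compositional turnover** — for the remaining pairs, the Raup–Crick
   metric on Bray-Curtis against 9999 random assemblies from the regional
   pool, rescaled to RC ∈ [−1, 1].
   RC > +0.95 → **dispersal limitation**; RC < −0.95 → **homogenizing
   dispersal**; otherwise → **drift**.

The per-process fractions of community pairs are the headline result.
Around this core the package provides interaction-adjusted community
similarity (TINA/PINA — the generalized cosine of abundance vectors under
a co-occurrence or phylogenetic kernel), generalized UniFrac, Mantel tests
and distance-decay correlograms (1000-km classes), sequential
β-diversity with abrupt-change flags (0.8/0.7 presets), PERMANOVA,
variance partitioning and LCBD.

## Worked example

Simulate a dispersal-limited metacommunity (20 stations, 300 taxa, 10⁴
individuals per station, dispersal decay length 500 km) and recover the
processes that built it:

```r
library(ecoassembly)

cfg <- regime_config("dispersal_limitation", seed = 42)
sim <- simulate_metacommunity(cfg)
sim
#> Synthetic metacommunity: 20 stations x 300 taxa, J = 10000
#>   selection s = 0 (tau = 0.5), dispersal lambda = 500 km, pool = logseries
#>   regime: dispersal_limitation

counts <- sim$counts[, colSums(sim$counts) > 0]
tree   <- ape::keep.tip(sim$tree, colnames(counts))

q <- quantify_assembly_processes(counts, tree,
       thresholds = process_thresholds(n_null_bnti = 999, n_null_rc = 999),
       seed = 42)
q
#> Assembly-process quantification
#>   heterogeneous_selection     6 pairs    3.2%
#>   homogeneous_selection       0 pairs    0.0%
#>   dispersal_limitation      108 pairs   56.8%
#>   homogenizing_dispersal      5 pairs    2.6%
#>   drift                      71 pairs   37.4%
```

56.8% of station pairs are attributed to dispersal limitation — the
process the generator actually used (no selection, λ = 500 km); the
near-neighbour pairs that still exchange migrants fall into the drift
band, as they should. `autoplot(q)` draws the process-fraction bar chart,
and `tidy(q)` returns the per-pair table (βMNTD, βNTI, RC, label).

Dispersal limitation also leaves a spatial fingerprint — distance decay in
the first 1000-km class:

```r
dd <- mantel_correlogram(haversine_distances(sim$metadata),
                         bray_curtis(counts),
                         class_width_km = 1000, n_perm = 499, seed = 42)
head(dd, 4)
#> # A tibble: 4 × 6
#>   class_index class_midpoint n_pairs mantel_r p_value p_corrected
#>         <int>          <dbl>   <int>    <dbl>   <dbl>       <dbl>
#> 1           1            500      36    0.864   0.002       0.002
#> 2           2           1500      33    0.142   0.02        0.02
#> 3           3           2500      29   -0.146   0.012       0.024
#> 4           4           3500      25   -0.235   0.002       0.008
```

Community similarity decays strongly within the first distance class
(Mantel r = 0.86, corrected p = 0.002) and the correlation declines and
turns negative with distance — the classic distance-decay correlogram.
`autoplot(dd)` plots it with significant classes filled.

For real data the entry points are `read_otu_table()`, `read_tree()` and
`run_pipeline(pipeline_config(...))`, which chains preprocessing
(rarefaction to a common depth, low-abundance filtering), the
phylogenetic-signal check, process quantification, β-diversity/TINA/PINA
matrices and the spatial statistics into one seeded, provenance-stamped
report bundle.

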