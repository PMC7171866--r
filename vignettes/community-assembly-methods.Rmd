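---
title: "Quantifying selection, dispersal and drift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying selection, dispersal and drift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

## The inference problem

Microbial metacommunities are shaped by a small set of ecological
processes: **selection** (deterministic fitness differences imposed by the
environment, which can either constrain — *homogeneous selection* — or
promote — *heterogeneous selection* — divergence between communities),
**dispersal** (movement of organisms, ranging from *homogenizing dispersal*
at high rates to *dispersal limitation* at low rates), and **ecological
drift** (stochastic changes in relative abundances). None of these is
observable directly from a survey; they must be inferred from the imprint
they leave on compositional and phylogenetic turnover.

`ecoassembly` implements the two-step null-model framework that performs
this inference from an OTU/ASV count table and a phylogeny of the taxa,
together with the interaction-adjusted β-diversity indices (TINA/PINA) and
the spatial statistics (distance-decay correlograms, PERMANOVA, variance
partitioning, LCBD, sequential β-diversity) used to corroborate it, and a
synthetic metacommunity generator with known ground truth for validating
the whole chain.

## Step 1: selection from phylogenetic turnover

The premise is that habitat preference is phylogenetically conserved: close
relatives have similar environmental optima. This must be *checked*, not
assumed — `phylo_signal_correlogram()` estimates each taxon's niche value
as the abundance-weighted mean of an environmental variable over the
samples it occupies, and relates between-taxon niche distance to cophenetic
distance in a Mantel correlogram with progressive Holm correction. A
significantly positive correlation in the shortest phylogenetic distance
class licenses the interpretation of the next statistic; `run_pipeline()`
logs a prominent warning when it is absent.

Phylogenetic turnover between two communities *k* and *m* is measured by
the abundance-weighted **β mean nearest taxon distance**,

$$\beta\mathrm{MNTD}(k,m) = \tfrac12\Big[\sum_{i \in k} f_{ik}\,
\min_{j \in m}\Delta_{ij} + \sum_{j \in m} f_{jm}\,
\min_{i \in k}\Delta_{ji}\Big],$$

where `f` are within-sample relative abundances and Δ the cophenetic
distances. The nearest-taxon search runs over the partner community's
present taxa *including a shared taxon itself* (at distance zero), so
identical communities score exactly 0.

The standardized effect size, the **β nearest taxon index** (`bnti()`), is
obtained by shuffling taxon identities (with their abundances) across the
tips of the phylogeny — one shuffle per randomization, reused for every
pair, which is both what the widely used reference scripts do and what
keeps 999 randomizations affordable; a pair-level option would differ only
in Monte-Carlo error. With 999 randomizations,
$\beta\mathrm{NTI} = (\beta\mathrm{MNTD}_{obs} - \mu_{null})/\sigma_{null}$,
and $|\beta\mathrm{NTI}| > 2$ is read as a significant departure: positive
values flag heterogeneous selection, negative values homogeneous selection.
Pairs with $\sigma_{null} = 0$ (possible on degenerate geometries such as
star trees) are reported as `NA` and excluded from summaries.

## Step 2: dispersal and drift from compositional turnover

Pairs not claimed by selection are passed to the abundance-aware
**Raup–Crick** metric on Bray-Curtis dissimilarities
(`raup_crick_bray()`). Each of 9999 null replicates assembles both
communities from the regional pool: a community's observed richness is
drawn without replacement with probability proportional to metacommunity
occupancy, each drawn taxon is seeded with one read, and the remaining
reads are allocated by a multinomial on metacommunity relative abundances.
(A literal reading of "allocate all reads by abundance" could leave a drawn
taxon with zero reads and break the richness constraint the null just
imposed; the one-read seeding is the standard resolution.) With
$RC = 2\,(RC_{raw} - 0.5) \in [-1, 1]$ and ties between null and observed
dissimilarity weighted ½, values above +0.95 indicate more turnover than
random assembly produces (dispersal limitation), below −0.95 less
(homogenizing dispersal), and the band in between is indistinguishable from
random assembly — drift. The `pool` argument lets the null draw its
occupancy and abundance weights from a reference table other than the one
being scored; the regional (all-sample) pool is the default.

`classify_processes()` applies the two steps in order and
`process_summary()` reports the fraction of community pairs per process —
the headline figure of this type of analysis.

### Calibration

Both null models are validated against their own null processes in the test
suite: tables generated independently of the phylogeny yield
$|\beta\mathrm{NTI}| > 2$ for 3–7% of pairs (450 pairs, 999
randomizations), and pairs assembled by the Raup–Crick null itself yield
approximately uniform $RC_{raw}$ with $|RC| > 0.95$ in 3–7% of pairs —
both consistent with the nominal 5% at the stated Monte-Carlo resolution.

## Interaction-adjusted β-diversity

Compositional indices ignore that taxa live in association networks. TINA
(`tina()`) scores two communities by the average association strength
between their members, as the generalized cosine

$$s(A,B) = \frac{\sum_{ij} p_{iA}\, p_{jB}\, a_{ij}}
{\sqrt{\sum_{ij} p_{iA}p_{jA}a_{ij}\; \sum_{ij} p_{iB}p_{jB}a_{ij}}},$$

with `a` a taxon-association kernel in [0, 1]. This self-similarity
normalized form is adopted because it reproduces the three analytic anchor
values exactly: identical communities give 1; disjoint communities with
neutral associations (a = 0.5) give 0.5; complete avoidance (a = 0) gives
0. The association kernel (`taxon_associations()`) is the Pearson (or
Spearman) correlation of relative-abundance profiles rescaled by
$a = (\rho + 1)/2$ — the published workflow this reconstructs used SparCC
correlations, whose inference is out of scope here; the estimator is
recorded in the output so results are labelled. Zero-variance taxa receive
the neutral association 0.5 rather than being dropped, keeping the taxon
set aligned with the other metrics. PINA (`pina()`) substitutes
phylogenetic similarity $1 - \Delta_{ij}/\max\Delta$ for the co-occurrence
kernel. Dissimilarities for downstream analyses are `1 - TINA`
(`as_dissimilarity()`).

## Spatial statistics

* `gunifrac()` — generalized UniFrac with moderation exponent α (default
  0.5, the usual compromise; α = 1 recovers normalized weighted UniFrac,
  which the tests exploit as an independent oracle).
* `mantel_test()` — Mantel correlation with one-sided permutation p
  (add-one rule), plus an exhaustive-enumeration mode over all $n!$
  relabelings for small n, used as its own oracle.
* `mantel_correlogram()` — distance-decay over contiguous distance classes
  (1000 km width by convention for basin-scale transects), indicator
  Mantel statistic per class, progressive Holm correction. When the class
  width places every pair in one class the membership indicator is
  constant and the statistic is undefined; the class is reported with `NA`
  and a warning.
* `permanova()` — sequential (Type I) McArdle–Anderson partitioning via
  `vegan::adonis2`; term order is a documented, required input. Collinear
  designs and constant factors are rejected before fitting.
* `variance_partition()` — principal-coordinate embedding (positive
  eigenvalues only) followed by RDA adjusted-R² inclusion–exclusion into
  pure environmental, pure geographic, shared and unexplained fractions;
  adjusted R² can legitimately be slightly negative and is reported as-is.
* `lcbd()` — local contributions to β diversity on Hellinger-transformed,
  column-centered abundances; per-sample shares sum to 1. The permutation
  test permutes each species' *transformed* values independently across
  samples (the transform is held fixed): this keeps the row-sum coupling
  of the raw counts out of the null and tests exactly the quantity being
  decomposed.
* `sequential_beta()` — dissimilarity of each station to its immediate
  predecessor in cruise order, with abrupt-change flags at a strict
  threshold (0.8 and 0.7 are the documented presets for picoeukaryotes and
  prokaryotes on Bray-Curtis; both are parameters, not constants).

## The synthetic metacommunity generator

No public generative model exists for this inference chain, so the
generator is the package's own construction, built from the processes the
framework is meant to detect:

1. **Phylogeny**: pure-birth tree rescaled to unit depth
   (`simulate_tree()`).
2. **Niches**: Brownian motion along branches
   (`evolve_niche()`; child = parent + N(0, σ²·branch length)), giving tip
   variance σ²·depth and a positive trait–phylogeny correlation — the
   phylogenetic signal the framework requires.
3. **Selection**: Gaussian fitness $w_i(E) = \exp(-(E-\mu_i)^2/2\tau^2)$
   raised to the exponent *s*; one knob interpolating from neutral (s = 0)
   to hard filtering.
4. **Dispersal**: each taxon has one source station; immigration decays as
   $\exp(-d/\lambda)$ on great-circle distance. (A formulation in which
   every station is a source of every taxon cancels across taxa and leaves
   no spatial signal, so the single-source form is used; λ = ∞ recovers a
   well-mixed pool.)
5. **Drift**: station composition is drawn from a Dirichlet distribution
   with concentration $I\,p$ around the deterministic expectation, with
   $I = mJ/(1-m)$ the pool-coupling of the Sloan neutral community model,
   before the multinomial census of J individuals. A single multinomial at
   J = 10⁴ is census noise, not ecological drift — its Bray-Curtis
   turnover (~0.04) sits far below the Raup–Crick null's own assembly
   variability (~0.15), so a neutral metacommunity would be misread as
   homogenized. The default `immigration_m = 0.01` is within the range
   reported for marine bacterioplankton in the neutral-model literature;
   `immigration_m = 1` disables drift and recovers the pure multinomial.
6. **Pool**: Fisher log-series ranks (many rares, the shape of real
   surveys) or uniform.

Stations default to a 1-D equatorial transect with 500 km spacing — a
cruise-track abstraction that supports sequential β-diversity and 1000-km
distance classes. Defaults (300 taxa, 20 stations, J = 10⁴) keep a full
process quantification with 999 + 999 randomizations under a minute on one
CPU; the validation suite runs the four regime presets at exactly these
sizes.

### What the generator does and does not emulate

It reproduces the statistical structure the inference assumes:
phylogenetically conserved optima, environmental gradients, distance-
decaying immigration, drift, and log-series abundance. It does not emulate
ocean circulation, temporal dynamics, speciation, read-depth variation or
compositional artifacts of amplicon sequencing. Passing the
parameter-recovery tests therefore shows the *inference chain* is sound
under its own assumptions — not that those assumptions hold in any
particular ocean dataset.

### Regime presets and identifiability

`regime_config()` encodes four textbook regimes. Three are
straightforward: neutral/well-mixed (recovered as drift), strong selection
on a steep gradient (recovered as heterogeneous selection), and a short
dispersal decay length (recovered as dispersal limitation, with
first-distance-class decay in ≥ 90% of replicate metacommunities).

Homogeneous selection deserves its own paragraph, because it exposes a
real identifiability limit of the framework. The tip-shuffle null is
conditioned on the *observed regional table*. If the environment is
perfectly uniform across the region, that table is itself the filtered
clade: random relabelings within an already-filtered pool reproduce the
observed clustering, and βNTI cannot drop below −2 no matter how strong
the filtering (we measured 0–2% of pairs across wide parameter ranges;
what little signal remains is pushed *positive* by filter-tail outliers).
Homogeneous selection is detectable only when the regional pool spans more
environmental variation than the compared pairs — which is exactly the
situation in real surveys, where the metacommunity straddles habitats. The
preset therefore uses a dominant habitat (85% of stations at one optimum)
plus a small contrasting habitat that anchors the regional pool, moderate
filtering (s = 2, τ = 0.7) and strong drift churn (m = 0.001) so that
same-habitat pairs turn over clade members. Even so, recovery in this
direction is intrinsically weaker than for heterogeneous selection — the
well-known power asymmetry of nearest-taxon statistics between detecting
clustering and detecting overdispersion — and the validation asserts the
modal *selection* call, not an outright majority of all pairs.

## Numerical and interface choices

* Threshold comparisons (`|βNTI| > 2`, `|RC| > 0.95`, abundance classes
  0.1%/0.001%, occupancy classes 80%/20%, abrupt-change thresholds) are
  strict inequalities; equality falls on the conservative side.
* RC null-vs-observed comparisons use exact float equality for ties —
  meaningful because rarefied counts at equal depth make identical
  dissimilarities structurally possible.
* Rarefaction (`rarefy()`, default 4060 reads; ASV tables are commonly
  rarefied to 20000 — depth is a parameter, not a constant) drops samples
  below depth rather than resampling with replacement, and logs them.
* All stochastic functions take explicit integer seeds; the pipeline
  derives per-stage seeds from one master seed, so reruns are
  bit-identical. Every output file carries the package version, a config
  hash and the master seed.
* Distance functions return `stats::dist` objects labelled by sample id;
  similarity matrices carry a `kind` attribute and unit diagonal. Result
  tables are tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Known limitations

* Process fractions are whole-assemblage summaries; per-lineage
  attribution is out of scope.
* The Raup–Crick regional pool is estimated from the samples at hand; very
  uneven survey designs bias occupancy weights.
* The homogeneous-selection direction of βNTI has intrinsically low power
  at desk-scale richness (see above); real-data analyses mitigate this
  with pools of thousands of taxa.
* The TINA association kernel here is a correlation estimator, not a
  compositional network inference; strongly compositional data may warrant
  an external association matrix, which `tina()` accepts directly.
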