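Package: ecoassembly
Title: Quantifying Selection, Dispersal and Drift in Microbial Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Null-model quantification of the ecological processes that
    structure microbial metacommunities from OTU/ASV count tables and a
    phylogeny: phylogenetic turnover (beta mean nearest taxon distance and
    its standardized effect size, the beta nearest taxon index),
    abundance-aware Raup-Crick null models on Bray-Curtis dissimilarities,
    and the resulting five-way classification of community pairs into
    heterogeneous/homogeneous selection, dispersal limitation, homogenizing
    dispersal and drift. Also provides interaction-adjusted community
    similarity (TINA/PINA), generalized UniFrac, sequential beta-diversity,
    distance-decay Mantel correlograms, PERMANOVA, variance partitioning and
    local contributions to beta diversity (LCBD), plus a seeded synthetic
    metacommunity generator with phylogenetically conserved niches,
    environmental gradients, distance-limited immigration and multinomial
    drift for end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
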