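Package: pollinet
Title: Quantitative Plant-Pollinator Network Analysis Along Urbanisation Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative bipartite plant-flower-visitor network
    analysis in urban landscapes: network construction from long-format
    visitation records at species and genus resolution, the five classical
    network metrics (connectance, NODF nestedness, Barber-type quantitative
    modularity by simulated annealing, network specialisation H2', and
    species-level specialisation d'), fixed-margin (Patefield) null models
    with delta-standardisation of metrics, a building-height-modified Hanski
    habitat connectivity index, scale-of-effect selection for multi-radius
    landscape predictors, community composition preprocessing with
    permutation-based environmental vector fitting, and a regression stage
    with collinearity screening, a Poisson/negative-binomial model ladder,
    bounded all-subsets AIC selection and spatial autocorrelation
    diagnostics. A seeded synthetic-data generator emulates an 11-site urban
    dry-grassland study design so the full pipeline runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    ape,
    vegan
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
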