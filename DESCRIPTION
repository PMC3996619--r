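Package: reefwaves
Title: Dating Waves of Habitat Colonization on Time-Calibrated Phylogenies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the absolute timing of habitat colonization on
    time-calibrated ultrametric phylogenies. Resamples binary habitat states
    from per-family incidence percentages, fits a two-state continuous-time
    Markov (Mk) model with discretized priors on rate and asymmetry, draws
    stochastic character maps, bins transition ages per million years
    against a tip-shuffle null to locate colonization waves, measures
    phylogenetic clustering of habitat states with the net relatedness
    index, and profiles morphological disparity through time against a
    Brownian-motion null using phylogenetic principal components. A
    synthetic-data generator (birth-death trees, forward Markov histories
    with time-windowed rates, Brownian and Ornstein-Uhlenbeck trait
    evolution, habitat percentage mixtures) provides known ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    picante,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
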