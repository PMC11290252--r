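Package: copevolve
Title: Trait-Based Evolutionary Simulation of Copepod Diapause Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-based simulation of the evolution of diapause-exit
    timing in the high-latitude copepod Calanus finmarchicus. The day of year
    on which adults return from overwintering dormancy is a heritable trait
    with a mean and a phenotypic variance; multi-generation simulation under
    seasonal food and temperature forcing, with stochastic temperature-
    dependent predation, lets optimal exit timing and bet-hedging variance
    emerge by selection. Includes a synthetic seasonal-forcing generator,
    a deterministic daily bioenergetic life-history core with precomputed
    trajectory lookup, stage-specific stochastic mortality, the selection
    engine with frequency-preserving resampling, post-convergence phenology
    diagnostics, and command-line experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
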