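Package: pathppa
Title: Predictive Power Analysis of Interface Path Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis of transition-(interface-)path-sampling
    data. Quantifies how well candidate collective variables predict reaction
    success via the predictive capacity, computed from reactive/unreactive
    first-crossing densities estimated by Savitzky-Golay differentiation of
    weighted integrated histograms. Includes closed-form WHAM path reweighting
    across nested interface ensembles, crossing-probability/flux/rate assembly,
    index-invariant distance-matrix descriptors with switching-function and
    angular collective variables, simulated-annealing search over linear
    combinations of collective variables, and a seeded double-well Langevin
    path-ensemble generator providing direct-counting oracles for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
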