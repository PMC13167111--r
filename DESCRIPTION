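Package: phenodrift
Title: Bet-Hedging and Within-Lifetime Phenotypic Drift in Fluctuating
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyze drifting individual behavioral
    biases and to evaluate when within-lifetime phenotypic drift versus
    developmental bet-hedging is adaptive. Includes generators for synthetic
    behavioral panels, arena tracks and gappy time series; turn-direction
    kinematics, Blackman low-pass filtering and Lomb-Scargle spectra with
    bootstrap confidence intervals; a hierarchical Bayesian AR(1) model of
    daily turn bias fitted by a blocked Gibbs sampler with posterior
    group comparisons; an analytically tractable two-state (and N-state)
    phenotype-switching model; a deterministic age-structured population
    simulator over a binned preference axis driven by fluctuating
    environments; band-limited environment generation and real-series
    preprocessing; and fitness-landscape sweeps with principal components
    analysis across landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    coda
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
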