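Package: baymap
Title: Bayesian Disease Mapping of Small-Area Cancer Risk with BYM Smoothing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Small-area disease mapping for areal count data: rook-contiguity
    adjacency graphs with GAL and GeoJSON interchange, internal indirect
    standardization of incidence and mortality counts, a
    Metropolis-within-Gibbs sampler for the Besag-York-Mollie (BYM) Poisson
    log-linear model with an intrinsic conditional autoregressive spatial
    prior, single-chain convergence diagnostics (Geweke z, autocorrelation,
    effective sample size), credible-interval hotspot classification of
    smoothed standardized incidence and mortality ratios, and global and
    local Moran's I with Monte Carlo permutation inference. Includes a
    synthetic-data module that emulates a cancer-registry cohort and
    spatially correlated areal counts so the whole pipeline is testable
    without restricted registry data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
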