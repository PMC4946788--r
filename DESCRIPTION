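Package: sseDetect
Title: Detection of Repeated Sequences of Synchronous Spike Events in
    Parallel Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical detection of repeated sequences of synchronous
    spike events (SSEs) in massively parallel spike trains. Time is
    discretized into bins and a bin-by-bin intersection matrix is formed
    whose entries count the neurons active in both bins; a repeated SSE
    appears as a diagonal structure of large entries. Each entry is
    assessed against an independent-Poisson null via the exact
    Poisson-binomial distribution or its Le Cam (Poisson) approximation,
    the joint significance of the largest entries inside a
    diagonally-oriented rectangular kernel is evaluated through the joint
    survival function of order statistics, and significant entries are
    clustered into diagonal structures with a density-based scan under an
    anisotropic elliptical metric. The package also provides firing-rate
    estimators (PSTH, fixed-width and optimized-bandwidth kernel
    convolution), bin-shuffling Monte-Carlo surrogates, a suite of
    stochastic background models for validation (stationary and
    non-stationary Poisson, gamma renewal, rate-jump propagation,
    compound Poisson population synchrony, multiple single-interaction
    processes), and benchmarking utilities with true/false-positive
    classification rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
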