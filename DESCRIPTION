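Package: rangeen
Title: Range Entropy and Self-Similarity Analysis of Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-complexity analysis for univariate biomedical time series.
    Implements range entropy (RangeEnA and RangeEnB), amplitude-robust
    modifications of approximate entropy and sample entropy in which the
    Chebyshev template distance is replaced by a normalised range distance
    bounded in [0, 1], alongside reference implementations of approximate and
    sample entropy themselves. Includes rescaled-range (R/S) Hurst-exponent
    estimation, seeded simulators for white/pink/brown noise, fractional
    Brownian motion (exact Cholesky method) and fractional Levy motion,
    entropy profiling over tolerance and embedding-dimension grids with
    r-/m-exponent line fits linking entropy to the Hurst exponent, and a
    config-driven experiment runner with plain-text I/O for single-channel
    EEG-style segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
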