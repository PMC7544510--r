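Package: vrplace
Title: Place Coding, Theta Phase and Population Decoding in Virtual Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous CA1/V1 recordings during
    virtual-corridor navigation under gain manipulation. Provides spatial
    response profiles with circular-shift permutation tests, gain-shift
    estimation and variance decomposition, theta-phase statistics (modulation
    index, pairwise phase consistency, phase-by-position drift and sinusoid
    fits, layer-stratified permutation tests), independent-Poisson Bayesian
    population decoding with cross-validation and jackknife errors,
    V1-CA1 decoding-error coupling with position/speed-conditioned shuffles,
    and a two-step orthogonalized ridge regression attributing spike counts
    to position and behavioral covariates. A synthetic session generator with
    full ground truth (field anchoring between visual and wheel-distance
    coordinates, sinusoidal theta modulation and precession, inhomogeneous
    Poisson spiking) makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
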