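Package: chaosEEG
Title: Nonlinear Dynamics Features and Self-Organizing-Map Classification
    of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chaos-theoretic and spectral characterisation of multichannel
    EEG-like recordings, and classification of mental-task states from the
    resulting features. Implements delay-coordinate and multi-lead phase-space
    reconstruction, the central tendency measure (CTM) of the second-order
    difference plot of tangent-vector angles with an IAAFT surrogate-data
    determinism ratio, approximate entropy, the Grassberger-Procaccia
    correlation dimension with automatic scale-free-region detection, the
    largest Lyapunov exponent by the small-data-sets (Rosenstein) method,
    Burg autoregressive power spectra with AIC order selection and alpha/beta
    band energies, and a from-scratch two-dimensional self-organizing map.
    Includes generators for canonical chaotic and stochastic test signals and
    for labelled synthetic multichannel recordings, plus an end-to-end
    feature-extraction and classification pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
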