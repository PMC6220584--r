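Package: pulsekernel
Title: Temporal Weighting Kernels for Pulse-Based Motion Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Psychophysical reverse correlation for pulse-based motion
    discrimination: simulation of pulsed motion stimuli with time-varying
    mean strength (flat, early, late conditions, zero-mean and frozen-seed
    trials), synthetic decision-making observers (linear kernel, bounded
    accumulation, leaky integration, extrema detection), maximum-likelihood
    psychometric fitting with lapse rate, ridge-penalized logistic
    estimation of temporal weighting kernels with evidence-optimized
    regularization, and session-level summaries (kernel slope and energy,
    group comparisons, extrema-detection control, quality control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
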