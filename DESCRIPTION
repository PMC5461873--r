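Package: deepactive
Title: Deep Temporal Active Inference for Discrete State-Space Generative Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hierarchical ("deep temporal") active inference for discrete-state
    generative models. Builds and validates multi-factor likelihood (A),
    transition (B), preference (C) and initial-state link (D) arrays, performs
    variational belief updating by gradient descent on free energy with
    expected-free-energy policy selection, and schedules belief updates
    asynchronously across hierarchical levels so that one higher-level state
    transition spans a whole lower-level sequence. Includes a two-level model of
    reading (sentences generating words generating letters sampled by saccades),
    simulated electrophysiology (firing-rate rasters, band-pass filtered local
    field potentials), and classical violation analyses producing mismatch
    negativity and P300-like difference waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
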