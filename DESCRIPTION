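Package: prestim
Title: Pre-Stimulus Oscillatory Power, Event-Related EEG Dynamics, and
    Causal Mediation During Sequence Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how pre-stimulus oscillatory power shapes
    event-related synchronization (ERS) and desynchronization (ERD) during
    incremental sequence learning. Provides a synthetic multi-subject epoch
    generator with controlled aperiodic (1/f) background, subject-specific
    alpha oscillations and post-stimulus theta bursts; sliding-window
    Hanning-taper time-frequency decomposition; iterative spectral
    parameterization into aperiodic and Gaussian peak components with an
    R-squared quality filter; individual alpha frequency (IAF) detection and
    IAF-relative band definitions; dual baseline-correction schemes
    (per-repetition and per-subject) with the pre-stimulus activity term;
    a baseline-correction simulation study; behavioral scoring for the
    sequence-learning task; and causal mediation analysis (ACME/ADE) on
    linear mixed-effects models with cluster-bootstrap and quasi-Bayesian
    Monte-Carlo confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    rhdf5,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
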