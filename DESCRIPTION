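Package: entrainr
Title: Simulation and Analysis of Rhythmic TMS-EEG Alpha Entrainment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse concurrent TMS-EEG experiments that
    probe entrainment of intrinsic occipital alpha oscillations by short
    rhythmic pulse bursts. Provides a synthetic EEG generator built on
    phase-resetting alpha oscillators driven by rhythmic, arrhythmic and sham
    four-pulse trains; pulse-artifact interpolation, anti-aliased downsampling
    and epoching; five-cycle Morlet wavelet decomposition with evoked
    oscillation amplitude and inter-trial phase coherence (ITPC); planned
    time-window contrasts, topographic cluster-based permutation tests,
    pre-pulse phase-bin sinusoidal regression, repeated-measures ANOVA and
    individual-alpha-frequency correlation; and signal-detection psychophysics
    (d-prime, criterion, Naka-Rushton contrast-response fitting).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
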