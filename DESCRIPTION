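Package: ssvepr
Title: Frequency-Domain Analysis of Steady-State Visual Evoked Potentials
    with Reliable Components Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for steady-state visual evoked potential
    (SSVEP) acuity experiments: logMAR stimulus series and block/trial schedule
    design, a forward simulator of 128-channel EEG sessions with known
    ground-truth sources, the standard preprocessing chain (resampling to an
    integer number of samples per stimulus cycle, zero-phase band-pass
    filtering, bad-channel replacement, common average reference, threshold
    epoch rejection), exact bin-centered Fourier decomposition with coherent
    averaging of complex coefficients, Reliable Components Analysis (RCA)
    spatial filtering via a generalized eigenproblem on cross-trial
    covariances, neighbor-bin signal-to-noise statistics, and phase-based
    latency estimation with wrap-around candidate enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lmerTest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    broom,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
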