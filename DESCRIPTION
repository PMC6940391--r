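Package: phasescramble
Title: Phase-Scrambled Grating Stimulus Design and Neural Tuning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing families of phase-scrambled drifting-grating
    stimuli and for analysing calcium-imaging responses to them. Enumerates
    circular-unique phase sequences and scores their similarity to smooth
    motion (best-aligned sinusoid correlation, summed phase interval,
    spatiotemporal motion energy); renders stimuli as space-time movies and
    builds matched ideal linear kernels whose responses define a 10-stimulus
    reference frame; extracts trial-level dF/F responses from fluorescence
    traces; computes single-cell selectivity statistics (selectivity index,
    response projection index, orientation selectivity as one minus circular
    variance, Hotelling T-squared gating, double-Gaussian direction fits and
    the direction index); and performs population-level inference (bootstrap
    confidence intervals on before/after differences, covariate correlations,
    group t-tests and principal-component projection of 10-dimensional
    response vectors). A seeded synthetic-data generator emulates the
    statistical structure of two-photon recordings so the whole pipeline can
    be exercised without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    minpack.lm,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
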