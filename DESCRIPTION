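Package: dyadcoh
Title: Interbrain Wavelet Coherence Analysis for Dual-fMRI Hyperscanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dyadic (hyperscanning) fMRI experiments in
    which two interacting participants are scanned simultaneously. Computes
    magnitude-squared wavelet transform coherence between paired region-of-
    interest BOLD time series using the analytic Morlet wavelet, selects an
    empirical frequency band of interest from the dyad-averaged coherence
    spectrum, extracts per-block coherence terms with hemodynamic-delay
    exclusion, corrects them against a surrogate ("fake dyad") permutation
    baseline, and runs per-ROI repeated-measures ANOVA with Greenhouse-Geisser
    correction and Benjamini-Hochberg false-discovery control. Includes a
    synthetic-cohort generator with known ground-truth coupling and the scoring
    rules of the underlying joint button-press task, so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    e1071
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
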