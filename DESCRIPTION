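Package: glmspectrum
Title: Multilevel General Linear Model Spectrum Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates frequency spectra of continuous recordings by replacing
    the averaging step of the time-averaged (Welch) periodogram with a
    mass-univariate general linear model fitted across sliding-window
    short-time Fourier spectra. Supports condition, covariate and confound
    regressors with explicit semantics, contrasts with cope-, varcope- and
    t-spectra, Cohen's f-squared effect sizes, model-projected spectra,
    fixed-effects group-level modelling of stacked first-level results, and
    non-parametric cluster-based permutation inference over the
    frequency-by-channel grid. Includes a synthetic-data generator producing
    oscillatory multichannel signals with 1/f background, condition-dependent
    oscillation amplitude, slow drifts, artefact bursts and ocular confound
    time courses, with full ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
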