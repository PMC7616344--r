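Package: caninehrf
Title: Species-Tailored Haemodynamic Response Function Estimation for Awake-Dog fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate a species-tailored haemodynamic response
    function (HRF) from awake-dog fMRI data: finite impulse response (FIR)
    deconvolution of region-of-interest BOLD time courses, Nelder-Mead
    optimization of a seven-parameter double-gamma HRF within plausible
    physiological bounds, model-fit comparison against the canonical human
    HRF (with and without temporal and dispersion derivatives) via exact
    Wilcoxon signed-rank tests, first-level GLM construction with
    framewise-displacement motion scrubbing, and permutation-based
    group-level inference. Includes a synthetic BOLD data generator
    emulating block and event-related visual paradigms with known ground
    truth, so the full pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
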