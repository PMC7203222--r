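Package: eemnpls
Title: Multiway N-PLS Regression and Preprocessing for Fluorescence
    Excitation-Emission Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for soft-sensor modelling of bioprocess cultures from
    fluorescence excitation-emission matrices (EEMs). Implements scatter and
    inner-filter-effect pre-processing of EEM grids (first-order Rayleigh
    excision, second-order Rayleigh interpolation, sub-diagonal zeroing,
    absorbance-based inner-filter correction), tri-linear N-PLS regression
    with missing-cell exclusion and regression-coefficient-map folding,
    nested double cross-validation with leave-one-out latent-variable
    selection, the modified Arnaud chlorophyll-a assay equation, and a
    synthetic EEM generator for end-to-end verification of every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
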