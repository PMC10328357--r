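Package: pyrocal
Title: Charring Temperature Calibration for Archaeological Charcoal from
    Mid-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the absolute burning temperature of archaeological
    wood charcoal from attenuated total reflectance Fourier-transform
    mid-infrared (ATR FT-MIR) absorbance spectra, using taxon-specific
    partial least squares (PLS1) calibration models trained on
    laboratory-charred reference wood. Implements the full chemometric
    workflow: spectral resampling onto a common wavenumber grid, standard
    normal variate and median-filter preprocessing, NIPALS PLS1 with
    leave-one-out cross-validation and AIC factor selection, variable
    importance for projection (VIP) profiles, permutation (randomised
    response) validation, group prediction with one-way ANOVA and Tukey
    HSD letters, and ubiquity-corrected quantification of charcoal
    assemblages. A seeded synthetic-spectrum generator reproduces the
    statistical structure of the calibration design so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
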