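Package: wetlandAGB
Title: Species-Level Aboveground Biomass Estimation of Wetland Vegetation
    from UAV RGB Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates aboveground biomass (AGB) of emergent wetland
    vegetation at the species level from unoccupied-aerial-vehicle (UAV)
    RGB orthomosaics. Computes seventeen visible-band vegetation indices
    (ExG, CIVE, COM2, VDVI and others), resamples imagery to the field-plot
    scale, extracts windowed plot features, selects predictors by Pearson
    correlation, fits linear, quadratic and exponential inversion models as
    well as a small feedforward neural network trained by
    Levenberg-Marquardt least squares, evaluates models by MAE, RMSE and
    the coefficient of determination, and applies the fitted model across a
    species mask to map biomass. Includes a synthetic scene generator with
    known ground truth so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
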