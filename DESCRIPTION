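Package: rgcmap
Title: Quantification and Topography of Retinal Ganglion Cell Loss in
    Ocular Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantifying ocular-hypertension damage in
    the mouse visual system from wholemount microscopy: automated cell
    detection and counting on frame montages, isodensity and fixed-radius
    neighbour topography maps, wedge-based sectorial and diffuse loss
    quantification, superior-colliculus innervation volumetry by
    polynomial fit and integration, intraocular-pressure inclusion
    filtering, and nonparametric cohort statistics. Includes a synthetic
    wholemount generator (inhomogeneous Poisson retinas, pie-shaped
    sectorial lesions, fluorescence tile rendering, collicular area
    profiles and pressure time series) so every stage is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
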