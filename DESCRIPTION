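Package: diveforage
Title: Dive Segmentation, Prey-Capture Detection and Foraging Metrics for
    Penguin Biologging Data
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for analysing combined GPS, time-depth and tri-axial
    acceleration records from diving seabirds.  Conditions GPS tracks (land
    and speed filtering, regular interpolation), corrects depth-sensor drift,
    segments dives at a surface threshold and derives per-dive phase
    parameters, computes vectorial dynamic body acceleration (VeDBA) as an
    activity proxy, classifies dives as benthic or pelagic against a
    bathymetry raster, detects prey-capture events from accelerometry with a
    radial-kernel support vector machine trained on labelled windows, and
    summarises per-dive foraging success and efficiency indices.  Includes a
    synthetic foraging-trip simulator with ground truth so the full chain is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
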