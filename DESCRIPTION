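Package: oceansdm
Title: Presence-Only Species Distribution Modelling for Pelagic Plankton
Version: 0.1.0
Authors@R: person("Ocean", "SDM Maintainers", email = "oceansdm@example.org", role = c("aut", "cre"))
Description: Maximum-entropy (MaxEnt-style) presence-only species distribution
    modelling for oceanic plankton, with hinge features and L1 regularization,
    classic envelope algorithms (Bioclim, Envelope Score, Environmental
    Distance), multi-algorithm consensus maps, and climate-scenario ensemble
    projection. Includes a synthetic-ocean generator (WOA-like gridded
    temperature, salinity and nutrient layers with monthly seasonality, a known
    true suitability surface, biased presence sampling and perturbed
    future-scenario layers) so the full pipeline runs and is testable without
    external downloads, plus ESRI ASCII grid I/O, regridding, unit
    harmonization, occurrence deduplication at grid resolution, bias-grid
    construction, AUC/cross-validation/jackknife evaluation and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
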