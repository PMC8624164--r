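Package: methanoniche
Title: Niche Envelope Models and Hydrogen-Limited Growth Estimates for Methanogens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise the coarse-scale environmental niche of
    methanogenic archaea and to bound their potential biomass in an ice-covered
    ocean. Implements the Bioclim envelope algorithm (percentile-score variant)
    with Pearson collinearity prefiltering of predictor rasters, partial-ROC
    model evaluation by bootstrap AUC ratios, per-variable response curves, and
    an overlay of published Enceladus ocean condition intervals on the fitted
    curves. A companion growth module estimates methanogen cell concentration
    from a serpentinisation hydrogen budget via Monod kinetics and its
    supply-limited linear solution, under whole-ocean and hydrothermal-stripe
    scenarios. A synthetic-data generator produces spatially autocorrelated
    environmental rasters and envelope-structured virtual-species occurrences
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
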