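Package: esdrought
Title: Drought Impacts on Gridded Ecosystem Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how meteorological drought reshapes the supply
    of, and interactions among, ecosystem services on an annual 1-km gridded
    landscape. Computes four services per cell and year (water retention from
    an InVEST-style retention adjustment of water yield, soil conservation
    from the Revised Universal Soil Loss Equation, carbon sequestration from
    net primary productivity, and food supply by NDVI-proportional
    disaggregation of municipal grain yields), classifies drought severity
    from the standardized precipitation-evapotranspiration index (SPEI),
    extracts constraint-line response boundaries and their derivative-based
    thresholds, maps per-cell Theil-Sen slopes with Mann-Kendall significance,
    clusters cells into service bundles with a self-organizing map, measures
    drought-stratified trade-off and synergy correlations, and attributes
    service variation to drivers with exact (subset-enumeration) Shapley
    values over a pluggable surrogate predictor. A seeded synthetic landscape
    generator with planted statistical structure makes every stage testable
    without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
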