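Package: coldsoil
Title: Snow-Cover, Freeze-Thaw and Proxy-Year Analysis of Shallow Soil
    Temperature in Boreal Forest
Version: 0.1.0
Authors@R:
    person("coldsoil", "maintainers", email = "coldsoil@example.org",
           role = c("aut", "cre"))
Description: Tools to test the "cold soil in a warm world" hypothesis from
    shallow soil-temperature logger networks and fused satellite imagery.
    Detects daily snow presence from diurnal soil-temperature range, derives
    snow seasons and freeze-thaw event counts, selects proxy baseline and warm
    years from monthly temperature anomalies against a 1961-1990 climatology,
    predicts fine-resolution reflectance on coarse-only dates with a
    STARFM-style spatiotemporal fusion, maps snow with NDSI/NDVI threshold
    rules, and quantifies year-by-site contrasts with nested-random-effect
    models.  A seeded synthetic-data generator emulates sensor campaigns,
    raster scene series and anomaly records with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
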