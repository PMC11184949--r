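Package: canopyuniformity
Title: Quantifying Crop Canopy Uniformity from UAV-Derived Trait Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify within-plot growth uniformity of densely sown
    crops (wheat in particular) from UAV-derived trait maps. Plot-level
    rasters of fractional vegetation cover, leaf area index, SPAD
    chlorophyll readings and plant height are discretised with a
    classification parameter (bin width) and summarised by a battery of
    entropy- and variance-based uniformity indices (Shannon entropy,
    Pielou, Alatalo, Sheldon, Heip, coefficient of variation). Includes
    NDVI valley-threshold vegetation segmentation, point-cloud percentile
    plant height, a small feed-forward trait regressor, correlation and
    multiple linear regression of uniformity against yield and biomass,
    frozen reference prediction equations, cultivar clustering with ANOVA,
    bin-width and spatial-resolution sensitivity sweeps, and a seeded
    synthetic field simulator so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
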