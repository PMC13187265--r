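Package: dendrodrought
Title: Dual-Proxy Tree-Ring Reconstruction of Atmospheric and Soil Drought
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds signal-free detrended tree-ring width chronologies and
    elevation-corrected tree-ring oxygen-isotope chronologies, calibrates
    linear transfer functions against growing-season vapor pressure deficit
    (VPD) and a standardized multi-month moisture index, and extends both
    drought targets over the full proxy period with calibration error bands
    and low-pass smoothing.  Reconstructed years are classified into severe,
    moderate and non-drought types by k-means clustering on either index or
    on the combined matrix, and growth responses per drought type are
    quantified by superposed epoch analysis with a Monte-Carlo null.  A
    seeded synthetic-data module generates multi-tree proxy and climate
    series with known transfer functions so that every stage of the pipeline
    is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr
Config/testthat/edition: 3
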