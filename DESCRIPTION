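Package: forestchange
Title: Forest Loss Mapping from Multi-Date Multispectral Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping forest cover, dominant leaf type and
    year-to-year forest loss (woody-to-non-woody conversion and burnt forest)
    from Sentinel-2-like 10-band surface-reflectance stacks. Includes a
    synthetic-scene generator with known truth, seasonal median compositing,
    NDVI/NBR differencing with a 3-standard-deviation candidate mask,
    rule-based stratified reference sampling with automatic spectral
    verification, two-stage random-forest classification with cross-scene
    model transfer, direct change classification with a minimum-mapping-unit
    filter, error-matrix accuracy assessment, and regional area reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    randomForest,
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
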