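Package: amphex
Title: Species Exposure to Heat Waves, Cold Spells, and Droughts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies species-level exposure to increases in climatic
    extreme events. Detects heat-wave and cold-spell events from gridded
    daily temperature (percentile run-length definitions) and severe
    droughts from monthly SPEI fields, builds decadal difference fields and
    binary hazard layers, overlays species range polygons to classify
    per-species exposure, aggregates exposure by taxon, grid cell and
    country, and links exposure to Red List status transitions through a
    multinomial logistic regression reported as odds ratios. Ships a
    synthetic-data generator with known ground truth so the full pipeline
    is testable end to end.
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
    ncdf4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    geosphere,
    data.table,
    knitr,
    rmarkdown
Config/testthat/edition: 3
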