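Package: pollvalue
Title: Valuation, Vulnerability and Mapping of Crop Pollination Benefits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for the monetary valuation of the pollination-
    attributable share of crop production from country-by-crop-by-year
    panels of production quantities and producer prices, with inflation
    and purchasing-power-parity correction. Decomposes benefit series
    into quantity and price signals, computes national vulnerability
    indicators (pollination benefit as a share of GDP and of agricultural
    GDP), country-level linear trends and their correlations, and builds
    fine-resolution gridded benefit maps on a latitude-longitude lattice
    with country-zone price assignment and explicit missing-data
    semantics. Includes trend-surface generalized additive regressions of
    the mapped benefits on climate and cropland, and a seeded synthetic-
    data generator with construction-known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    mgcv,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
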