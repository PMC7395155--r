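Package: whaledens
Title: Whale Density from Satellite Imagery and Ship Line-Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates baleen-whale density from two platforms and compares
    them: a ship line-transect survey analysed by multiple-covariate distance
    sampling (half-normal and hazard-rate detection functions, AIC model
    selection, Cramer-von Mises goodness of fit), and counts of scored
    features of interest (FOIs) in very-high-resolution satellite imagery
    classified by a 13-criterion weighted score. Satellite counts are
    corrected for surface-availability bias using suction-cup tag depth
    records, with delta-method propagation of the coefficients of variation.
    Includes a synthetic-data generator (spatial point process, dive-cycle
    renewal model, detection thinning, criterion-score emission) so the full
    pipeline is testable end to end without proprietary imagery or embargoed
    survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
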