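Package: grazemap
Title: Spatial Modelling of Livestock Grazing Intensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map where and how intensively rangeland is grazed.
    Converts net primary productivity and land cover into a raster of
    annual grazeable energy, turns district livestock statistics into
    settlement-level grazing energy demand via herd age disaggregation and
    fodder accounting, distributes that demand onto the landscape with a
    competitive radius-expanding greedy allocation, calibrates district
    off-take rates against a maximum-grazing-distance criterion, and
    evaluates production-expansion scenarios. Includes a synthetic
    landscape generator for testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
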