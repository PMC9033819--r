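Package: maeeq
Title: Mining-Area Eco-Environmental Quality Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the eco-environmental quality of coal-mining regions from
    stacks of co-registered indicator rasters. Standardizes quantitative and
    qualitative indicators to [0,1], estimates indicator weights by
    genetic-algorithm projection pursuit, maps a weighted eco-environmental
    quality index graded with exact Jenks natural breaks, quantifies spatial
    structure with global and local Moran's I (LISA cluster maps under
    conditional permutation), attributes drivers with the geographic detector
    (factor, interaction and risk detection), and converts significant LISA
    clusters into management, close-attention and protective zones. Ships a
    seeded synthetic raster-scene generator with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
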