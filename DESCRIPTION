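Package: montaneN
Title: Elevational Gradients in Tropical Montane Forest Soil Nitrogen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing elevational gradients in tropical forest
    soil nitrogen. Classifies montane terrain from digital elevation models
    using slope and local elevation range, fits linear mixed-effect models
    of soil nitrogen concentration, C:N ratio and delta-15N against
    elevation and climate, derives apparent temperature sensitivity (Q10)
    from exponential temperature-response fits, and upscales soil nitrogen
    pools over gridded landscapes with t-based confidence intervals. A
    synthetic-data generator produces landscapes and transect sample tables
    with the statistical structure the analysis assumes, so the full
    pipeline is testable without any external download.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
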