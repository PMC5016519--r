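Package: stormquant
Title: Quantitative Analysis of dSTORM Localization Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative single-molecule localization microscopy
    (dSTORM) of plasma-membrane labeling: reading and writing localization
    coordinate tables, sliding-window localization-density maps, blink
    calibration of the localizations-per-fluorophore conversion factor and
    experimental localization precision from diluted reference samples,
    conversion of localization densities to detected molecular densities, and
    Ripley's h spatial statistics with Monte-Carlo envelopes from Poisson and
    Neyman-Scott null models. Includes seeded generators for synthetic
    localization data (complete spatial randomness, blinking fluorophores,
    double membranes, vesicle projection artifacts) for calibration and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
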