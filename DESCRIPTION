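Package: ceustic
Title: Time-Intensity Curve Analysis for Contrast-Enhanced Ultrasound of
    Machine-Perfused Kidneys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of contrast-enhanced ultrasound (CEUS)
    time-intensity curves recorded during normothermic kidney machine
    perfusion. Reads per-frame region-of-interest intensity tables, detects
    contrast arrival, smooths each curve by local quadratic regression with
    tricube weights, extracts peak intensity, time-to-peak, area under the
    curve and time-to-fraction-of-peak, combines peak and time-to-peak
    z-scores into region and overall CEUS scores, and correlates metrics
    and scores with perfusion outcomes by Pearson correlation. Includes
    region-of-interest mean-intensity extraction from cine image stacks, a
    gamma-variate bolus simulator with ground truth for end-to-end testing,
    report plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
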