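Package: somnpose
Title: High-Resolution Sleep Position Monitoring and Positional
    Desaturation Analysis from Triaxial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn raw chest-worn triaxial accelerometry into
    calibrated high-resolution sleep and stand angles, classify discrete
    sleep positions (supine, prone, left, right, standing), detect blood
    oxygen desaturation events from pulse-oximetry traces, compute
    angle-resolved positional statistics (percentage of time and of
    desaturation events per degree, local oxygen desaturation index, and
    the event/position ratio), derive supine-avoidance vibrotactile
    treatment schedules, and simulate full nights of wearable data with
    known ground truth for validation. Designed for the study of
    positional obstructive sleep apnea with a smartphone-class sensor
    strapped over the sternum and a finger pulse oximeter.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
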