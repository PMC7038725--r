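Package: stresspipe
Title: Wearable Stress Detection from Smartwatch HRV and EDA Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting perceived stress from
    wrist-worn wearable recordings. Reads Empatica-E4-style session exports,
    cleans interbeat-interval (IBI) series with a 20 percent successive-difference
    artifact rule and cubic-spline replacement, screens electrodermal activity
    (EDA) for motion artifacts, splits EDA into tonic and phasic components,
    extracts 13 heart rate variability and 2 x 7 EDA features per two-minute
    window, scores five-item ambulatory Perceived Stress Scale (PSS-5)
    self-reports, and evaluates lab-to-field model transfer across five
    training/testing configurations (LLKC, LLSR, DDSR, LDKC, LDSR) with five
    classifiers. Ships a seeded synthetic-study generator that emulates the
    signal, artifact and label-noise structure of a lab (TSST) plus
    daily-life (EMA) protocol so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
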