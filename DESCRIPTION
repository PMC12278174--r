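Package: freezeframe
Title: Adaptive Reverse Go/No-Go Inhibitory-Control Assessment Engine and
    Psychometric Validation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an adaptive reverse go/no-go assessment of speeded
    inhibitory control: a seven-level target-frequency staircase played in
    epochs of trials, with simulated respondents that convert latent
    inhibition ability into trial-level responses. Includes a synthetic
    cohort generator emulating a healthy older-adult baseline sample
    (correlated demographics, executive-function composite, latent ability,
    missing-completely-at-random scores) and the full validation pipeline:
    descriptives with skew and kurtosis, floor and ceiling quantification,
    Spearman and Pearson correlations, Wilcoxon rank-sum, and simple linear
    regression with an F test, assembled into a validation report with JSON,
    CSV and Markdown serialization and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
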