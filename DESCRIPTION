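Package: gnhpanel
Title: Twitter-Derived Gross National Happiness Indices and Dynamic Panel Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds daily national well-being time series from tweet streams
    using lexicon-based sentiment and emotion analysis: a 0-10 Gross National
    Happiness (GNH) index from the hourly balance of positive versus negative
    tweets, eight Plutchik emotion series, and three keyword-filtered context
    series (economic fear, institutional trust, loneliness-related sadness).
    Assembles a weekly country panel with epidemic covariates (cases per
    million under an inverse hyperbolic sine transform, policy stringency
    change dummies, residential mobility) and estimates a dynamic panel
    regression by OLS with restricted wild cluster bootstrap p-values using
    Webb six-point weights, suited to samples with few country clusters.
    Includes step-wise emotion selection, convergent-validity correlation
    tools, and a synthetic-data generator that makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    foreign,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
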