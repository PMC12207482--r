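Package: partnerbias
Title: Statistical Discrimination in Iterated Partner Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical and Monte-Carlo models of statistical discrimination
    emerging from iterated partner choice in a Stag hunt. Implements the
    closed-form/recursive model of a boundedly rational focal agent
    characterised by awareness, stickiness and color bias; the discrimination
    index measuring behavior-based versus color-based association; an
    agent-based simulator of the episode protocol (biased training
    communities, unbiased evaluation communities, perceptual-intervention
    signals); and parameter sweeps with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
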