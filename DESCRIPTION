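Package: mutpie
Title: Mutation Pie Charts, Completion Experiments and Distributions of
    Mutation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how mutational biases limit the
    discoverability of genotype-to-phenotype maps and the predictability of
    experimental evolution. Represents mutation spectra as mutation pie
    charts (MPCs) with Shannon-evenness, Gini and largest-share summaries;
    runs non-equiprobable coupon-collector completion experiments by exact
    simulation and closed-form even-case formulas; models absolute
    per-mutation rates as a log-normal distribution of mutation rates (DMR);
    calibrates the DMR dispersion parameter from an observed spectrum by
    simulation-based maximum likelihood with quantile-curve confidence
    intervals; and quantifies the repeatability of target-size advantages
    against DMR stochasticity. Ships the wrinkly-spreader mutation tables
    for Pseudomonas fluorescens SBW25 as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
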