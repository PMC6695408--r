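Package: prediasim
Title: Microsimulation of Prediabetes and Diabetes Progression with
    Lifestyle Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annual-cycle, individual-level microsimulation of glycemic
    progression (no diabetes, prediabetes, diabetes) in an adult population,
    with stratified Markov transition matrices estimable from longitudinal
    panel data, life-table mortality calibrated for diabetic individuals via
    a baseline-hazard shift, stochastic BMI drift, and one-year lifestyle
    interventions (DPP, DPP-YMCA, HELP-PD). Paired simulations with common
    random numbers yield incidence/prevalence/mortality improvements, averted
    cases, diabetes-free-survival gains, and cost-effectiveness accounting.
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
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
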