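Package: ccmdcea
Title: Distributional Cost-Effectiveness Analysis of Community-Based
    Pneumonia Treatment Scale-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic Markov cohort pipeline for sub-national
    distributional cost-effectiveness analysis of scaling up community-based
    treatment of childhood pneumonia (CCM). Region-level inputs (background
    infant and child mortality, pneumonia incidence, baseline treatment
    coverage, cost per treatment) drive a two-arm 120-cycle cohort model with
    half-cycle correction and discounting; background adult mortality is
    proxied by matching each region to a reference abridged life table with a
    similar under-five mortality rate. Outputs include life expectancy at
    baseline and target coverage, incremental cost-effectiveness ratios,
    under-five deaths averted, weighted Gini coefficients for interindividual
    and geographical inequality in life expectancy, and three scale-up
    scenario strategies (health maximization, equity-targeted, universal).
    Ships region-level inputs for Ethiopia's eleven regions derived from the
    2016 Demographic and Health Survey, and a synthetic-data module that
    generates reference life-table families and region tables for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
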