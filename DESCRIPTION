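Package: neocea
Title: Cost-Effectiveness Analysis of Neonatal Intensive Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic cohort model of neonatal intensive care for
    preterm infants, stratified by gestational age. Couples a neonatal-period
    decision tree (death, survival with no/minor/major disability) to a
    disability-stratified annual life table, computes life expectancy,
    disability-free life expectancy, discounted disability-adjusted life
    expectancy and discounted lifetime costs via ingredients-based costing,
    and reports incremental cost-effectiveness ratios against GDP-per-capita
    willingness-to-pay thresholds. Includes one-way (tornado) sensitivity
    analysis, bias-against-intervention scenario presets, Monte Carlo
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, and a synthetic-data generator for the demographic inputs
    (mortality schedule, background disability weights) that the model
    requires.
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
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
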