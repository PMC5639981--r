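Package: cheproj
Title: Projecting the Incidence of Catastrophic Health Expenditure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the country-level incidence of catastrophic
    health expenditure (CHE) to a future horizon year. Fits a linear mixed
    model on logit-transformed CHE incidence with country random intercepts
    and three macro-financial predictors (out-of-pocket share of health
    expenditure, health expenditure share of GDP, GDP per capita), projects
    covariates forward using annualised GDP growth by World Bank income
    group, and propagates parameter and estimation uncertainty through
    Monte Carlo simulation to obtain uncertainty intervals, financial-risk-
    protection target attainment probabilities, decline-rate distributions
    and gap-closing probabilities. Includes counterfactual policy scenarios
    (caps on the out-of-pocket share) and a synthetic country-panel
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    MASS
Config/testthat/edition: 3
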