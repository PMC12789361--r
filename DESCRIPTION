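Package: skillsim
Title: Dynamic Microsimulation of Labour Supply, Skill Demand and Mismatch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level dynamic microsimulation of a population's joint
    demographic, educational and labour-force evolution under skill-specific
    labour demand. Simulates fertility, mortality and migration by Monte Carlo,
    assigns educational attainment with an ordered-logit cohort model with
    intergenerational transmission, draws labour-force participation from a
    logistic model with immigrant-integration covariates, and allocates active
    individuals to unemployment or low-, medium- and high-skill jobs with a
    calibrated multinomial-logit occupation model driven by demand-to-labour-force
    ratios. Labour demand is projected as a fixed ratio to population with
    logit-linear skill-share trends. Ships a self-contained stylized-EU parameter
    bundle, a declarative what-if scenario engine (immigration, education,
    retraining, later retirement, automation, upskilling), and vacancy,
    underutilization and skill-mismatch accounting with tidy outputs and plots.
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
    MASS,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    knitr,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
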