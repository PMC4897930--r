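Package: microprev
Title: Micro-Area Prevalence Estimation from Pooled Complex Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Small-area estimation of behavioural risk factor prevalence
    (current smoking, excess bodyweight) from pooled cycles of a complex
    health survey. Fits a sex-stratified Besag-York-Mollie (BYM) spatial
    hierarchical logistic model by Markov chain Monte Carlo, post-stratifies
    posterior draws to micro-area census age-sex populations, flags areas
    whose prevalence exceeds the regional average with high posterior
    probability, classifies estimate precision by coefficient of variation,
    and corroborates elevated areas with a parametric-bootstrap Moran's I
    test and a Bernoulli elliptical spatial scan statistic. Ships a
    synthetic-data generator (lattice geography, census age-sex structure,
    area median income, pooled survey respondents with design and bootstrap
    replicate weights) so the whole pipeline is testable without access to
    confidential survey microdata.
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
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
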