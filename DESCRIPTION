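Package: pgstransmit
Title: Intergenerational Polygenic-Score Transmission Models for Twin Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural model of intergenerational polygenic-score (PGS)
    transmission for twin-family data. Separates direct genetic transmission
    (the effect of the alleles a child actually inherits) from genetic nurture
    (environmentally mediated effects of parental genetic background) while
    modelling the mother-father PGS correlation induced by assortative mating
    and residual population stratification. Provides full-information
    maximum-likelihood estimation under arbitrary missing-data patterns,
    likelihood-ratio tests and fit indices against saturated and independence
    models, standardized effects and a variance decomposition into direct
    transmission and nurture components, family-level nonparametric bootstrap
    confidence intervals, a generative simulator for power and calibration
    studies, and preprocessing utilities for symptom scoring and PGS
    covariate residualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    parallel
Config/testthat/edition: 3
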