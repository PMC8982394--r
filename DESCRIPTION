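Package: conidiomorph
Title: Inheritance Models and Dispersal Statistics for Conidiophore Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of natural conidiophore morphology in
    Neurospora crassa. Fits a hierarchy of three-locus epistatic multinomial
    segregation models to cross progeny counts by maximum likelihood using
    iteratively reweighted least squares (Fisher scoring), with nested
    chi-squared hypothesis tests, information-matrix standard errors, and
    heritability estimation. Also provides spore-dispersal statistics
    (two-sample Kolmogorov-Smirnov tests with exact lattice-path and
    asymptotic-series p-values, Shapiro-Wilk normality, and an
    order-statistic tail test on maximum dispersal distance),
    germination-rate and penetrance computations, and a seeded
    synthetic-data generator so every stage runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
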