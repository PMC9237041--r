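Package: decanalize
Title: Detecting Phenotypic Decanalization in Population Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect phenotypic decanalization -- locally heightened
    phenotypic variance -- of fasting glycemia in population survey microdata.
    Provides a synthetic survey generator with a known latent
    socioeconomic-disadvantage axis and a controllable variance effect,
    derivation of age-adjusted residual categories and income/glycemia
    categories, an optimal-scaling (PRINCALS-style) principal component
    analysis for mixed ordinal/nominal covariates, a k-nearest-neighbour
    running standard deviation over the component space with a permutation
    test for variance gradients, PERMANOVA and multivariate dispersion tests,
    a G-test of independence with per-cell contributions, and a pipeline that
    orchestrates the full workflow into a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
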