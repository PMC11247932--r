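Package: irtci
Title: Item Response Theory for Categorical Imputation
Version: 0.1.0
Authors@R: person("IRTCI", "Maintainers", email = "maintainers@irtci.example.org",
    role = c("aut", "cre"))
Description: Fits unidimensional item response theory models (two-parameter
    logistic for binary features, the graded response model for ordinal
    features, and the nominal response model for unordered categorical
    features) to a case-by-feature matrix containing missing cells, scores
    each case's latent trait by expected a posteriori (EAP), and imputes
    every missing cell with its most probable category. Includes the
    supporting machinery needed to benchmark such imputations: MCAR and MAR
    amputation of complete tables, Little's chi-square test of the MCAR
    assumption, quantile discretization of continuous features into ordinal
    ones, a response-matrix simulator with known item parameters, and
    imputed-cell F1 scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
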