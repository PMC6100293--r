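Package: pepqsar
Title: QSAR Modeling and Rational Design of Antioxidant Tripeptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for quantitative structure-activity relationship
    (QSAR) analysis of short antioxidant peptides. Parses AAindex1
    physicochemical property databases, encodes tripeptides as
    position-wise descriptor matrices, screens variables by stepwise
    regression with variance-inflation-factor diagnostics, fits multiple
    linear regression, partial least squares, support vector regression
    and random forest models with leave-one-out and k-fold
    cross-validation, maps per-residue positional contributions, scores
    candidate tripeptides for rational design, and quantifies free-radical
    assay readouts (DPPH, TEAC, FRAP) from plate absorbances. Includes a
    seeded synthetic-data generator so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    car,
    mixOmics,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
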