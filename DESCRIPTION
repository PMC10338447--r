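Package: aggpsynet
Title: Penalized Ensembles and Network Models Linking Proneness to
    Aggression and General Psychopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying shared psychological
    characteristics of proneness to aggression and general psychopathology
    in community cohorts. Provides a latent-factor synthetic-cohort
    generator with ground truth, survey preprocessing (missingness filters,
    dummy coding, k-nearest-neighbour imputation with strict train/test
    separation), first-principal-component p-factor scoring, repeated
    subsampling LASSO/Elastic-Net ensembles with confidence-interval
    feature selection and cross-outcome prediction, parallel analysis and
    minimum-residual factor analysis with oblimin rotation, automatic
    normalizing-transformation selection, unregularized stepwise EBIC
    selection of Gaussian graphical models, and bootstrap stability
    analysis (edge intervals, expected influence, case-drop CS
    coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
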