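Package: cvdstage
Title: Skeletal Maturation Staging from Cervical Vertebra Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automated staging of skeletal maturation (pre-peak, peak,
    post-peak of mandibular growth) from lateral-cephalogram landmark
    coordinates on the third and fourth cervical vertebrae. Provides
    coordinate normalisation and Monte-Carlo landmark-error-reduced
    anterior-height to anteroposterior-length ratio measurement, feature
    engineering, class-conditional tabular data augmentation confined to
    per-class feature ranges, a stacking ensemble classifier over tuned base
    learners with a multinomial logistic meta-model, a weighted multiclass
    metric suite, and midpoint cutoff derivation between adjacent maturation
    classes, together with a synthetic cohort generator for end-to-end
    testing without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
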