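Package: dyadkin
Title: Kinematic and Postural Feature Analysis of Dyadic Point-Light Interactions
Version: 0.1.0
Authors@R: person("Movement", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying emotional body language in two-person
    point-light displays. Provides a data model and tabular I/O for dyadic
    15-marker motion-capture scenes, a calibrated synthetic scene and rater
    simulator, extraction of eight intrapersonal kinematic/postural features
    and twelve interpersonal proxemic, coordination and balance features,
    one-way ANOVA emotion-specificity statistics, bagged decision-tree
    emotion classification with balanced leave-one-per-category
    cross-validation and predictor importance, and a representational
    similarity analysis pipeline (model, feature, behavioural and
    combination dissimilarity matrices, Kendall tau-A, noise ceilings,
    multidimensional scaling, signed-rank comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
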