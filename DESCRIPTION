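Package: sasangface
Title: Facial Metrics, BMI and Sasang Constitutional Typing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Landmark-based facial morphometrics for Sasang constitutional
    medicine research. Computes the standard 2-D facial metrics (perimeter-to-
    area ratio, facial width-to-height ratio, cheek-to-jaw-width ratio, eye
    size, lower-face proportions, eyebrow height) from a 20-point landmark
    scheme, compares them across constitutional types with one-way ANOVA and
    Duncan multiple-range lettering, relates them to body mass index via
    Pearson correlations with Fisher-z comparison of correlation magnitudes,
    and discriminates the TaeEum (TE) type with logistic regression under
    exhaustive BIC-based Bayesian model averaging, c-statistic evaluation and
    leave-one-out cross-validation. A synthetic-data generator calibrated to
    published group summary statistics makes the whole pipeline testable
    without the original photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
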