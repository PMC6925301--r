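Package: traitrank
Title: Trait Filtering, SVM-RFE Ranking and Cross-Validated
    Classification for Image-Derived Plant Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase statistical workflow for high-throughput plant
    phenotyping trait tables. Phase one filters replicated image-derived
    trait measurements: zero-as-missing handling, Grubbs and
    Bonferroni outlier tests per replicate group, Pearson reproducibility
    screening, and stepwise variance-inflation-factor pruning of redundant
    traits. Phase two ranks the surviving traits by linear support vector
    machine recursive feature elimination (SVM-RFE, squared-weight
    criterion) and evaluates LDA, random forest, and linear/radial SVM
    classifiers over top-ranked trait fractions under repeated stratified
    k-fold cross-validation. Includes a two-class multivariate-normal
    trait simulator with a closed-form Bayes-accuracy oracle for
    calibration, and a reproducible experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
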