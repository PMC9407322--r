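Package: specdefect
Title: Defective-Fruit Detection from Vis-NIR Spectra with Oversampling and
    Metaheuristic-Tuned SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for classifying defective dried fruit (normal,
    starch-head and mildewed classes) from visible/near-infrared diffuse
    reflectance spectra. Provides a synthetic three-class spectra generator,
    multiplicative scatter correction, four minority-class oversamplers
    (random oversampling, SMOTE, borderline-SMOTE and ADASYN), CARS and SPA
    wavelength selection, a reptile search algorithm (RSA) and its modified
    variant (MRSA, Tent chaotic initialization plus Gaussian random-walk
    perturbation) alongside GA and PSO baselines for tuning the penalty and
    kernel parameters of an RBF support vector machine by cross-validated
    accuracy, and a multiclass evaluation suite (confusion matrix, macro
    recall/precision/F1 and kappa conventions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mixOmics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
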