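Package: kplsmwmr
Title: Kernel-PLS Maximum-Weight Minimum-Redundancy Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised feature selection for high-dimensional biomedical
    classification matrices by kernel partial least squares (KPLS) latent
    mapping, ReliefF feature weighting, Pearson-correlation redundancy, and
    an alpha-weighted maximum-weight/minimum-redundancy (MWMR) greedy
    criterion. Includes a Fisher-score baseline, a synthetic three-class
    benchmark generator, and an evaluation harness (repeated stratified
    k-fold cross-validation with a linear SVM; accuracy, Cohen's kappa,
    macro-F1) plus tidy() / glance() / autoplot() methods for every result
    type and a command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
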