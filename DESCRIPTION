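Package: coffo
Title: Chaotic Oppositional Fruit Fly Optimization and Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-space fruit fly optimization (FFO) and its chaotic
    oppositional variant (COFFO), which augments FFO with opposition-based
    population initialization, logistic-map chaotic sequences and a
    budget-shrinking chaotic local search around the global best. Includes a
    self-contained suite of CEC2019-style bound-constrained benchmark
    objectives, a binary wrapper feature-selection layer for classification
    data (V-shaped transfer functions, k-nearest-neighbour fitness under
    stratified cross-validation), a planted-subset synthetic data generator,
    and the nonparametric toolkit used to compare optimizers across problems
    (tied Friedman ranks, Friedman and Iman-Davenport statistics, Holm
    step-down post-hoc tests, exact Wilcoxon signed-rank tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    foreign
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
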