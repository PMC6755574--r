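Package: chemperf
Title: Fitting and Blocked Cross-Validated Assessment of QSAR Machine
    Learning Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modeling laboratory for cheminformatics and drug discovery:
    fits a suite of 13 machine learning methods to one or more named
    descriptor sets under repeated, seeded k-fold cross-validation in which
    every descriptor-set/method combination shares the same fold assignment
    (the blocking factor).  Out-of-fold predictions feed
    cheminformatics-oriented performance measures (initial enhancement,
    accumulation curves, AUC, sensitivity, specificity, PPV, F1, error rate,
    RMSE, R-squared, Spearman rho), a blocked two-way ANOVA with
    Tukey-Kramer multiplicity-adjusted pairwise comparisons rendered as a
    multiple-comparisons-similarity (MCS) matrix, and a Hotelling T-squared
    control chart for applicability-domain assessment of external compounds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    FNN,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
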