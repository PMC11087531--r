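Package: qibgwo
Title: Quantum-Inspired Binary Grey Wolf Optimization for Breast-Mass
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the grey wolf optimizer (GWO), its binary flag
    variant (BGWO), and an improved quantum-inspired binary grey wolf
    optimizer (IQI-BGWO) in which every wolf carries a per-dimension qubit
    register updated by y-axis rotation gates.  On top of the optimizers it
    provides the two applications they were designed for: tuning the error
    penalty and width of a lambda-scaled radial-basis-function support
    vector machine by cross-validated accuracy, and wrapper feature
    selection with a fitness that trades classification error against
    subset size.  A benchmark harness (ten classical test functions,
    repeated-trial statistics, Wilcoxon/Cohen's d/ANOVA/Tukey comparisons),
    confusion-matrix metrics with ROC curves, a MIAS-style mammogram
    preprocessing chain (PGM input, median filter, CLAHE, region-of-interest
    and patch extraction), and synthetic generators for phantom mammogram
    corpora and labelled feature tables make the whole pipeline testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    e1071,
    kernlab,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
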