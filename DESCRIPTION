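Package: grainfill
Title: Kinetics of Element Accumulation and Expression Trends in Developing Rice Grain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the accumulation of dry matter and mineral elements in
    developing cereal grain with three-parameter logistic kinetics, derives
    accumulation-rate curves with t-based confidence bands, and classifies
    elements into early, mid, and sustained accumulation patterns relative to
    the sampling window.  Computes net-accumulation and contribution-ratio
    budgets that apportion grain nutrients among vegetative source tissues
    (flag leaf, node I) and other sources, mines short time-series expression
    matrices for temporal profiles with exact permutation significance in the
    style of the Short Time-series Expression Miner, and provides the
    supporting group statistics (Z-scores, linear regression with Pearson
    correlation and confidence bands, one-way ANOVA with Tukey comparisons
    and compact letter displays).  A built-in synthetic-data generator
    emulates a grain-filling study design with known ground truth so every
    stage of the pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
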