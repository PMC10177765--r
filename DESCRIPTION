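Package: mutpanel
Title: Mutation Hotspot Panel Discovery and Burden-Based Cancer Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers highly mutated fixed-width genomic windows in somatic
    mutation catalogs, refines them into hotspot panels by one-way ANOVA and
    Tukey HSD selection, compares hotspot mutation burden across cohorts
    (Pearson correlation, Wilcoxon tests, fold changes, cold-spot control
    panels), and classifies sample cancer risk from hotspot burden plus
    personal risk factors with logistic-regression, neural-network and
    random-forest models. Includes a synthetic-cohort simulator with planted
    hotspots and full ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    glmnet,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
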