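Package: riparianPLS
Title: Gradient Analysis of Riparian Plant Functional Types by Partial
    Least Squares Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for space-for-time gradient analysis of riparian
    vegetation in Mediterranean headwater streams. Implements phytoclimatic
    aridity indices (UNEP PP/PET, de Martonne, Emberger Q2), Simpson
    diversity and cover-scale utilities; leaf-trait comparison of plant
    functional types by one-way ANOVA with Tukey-Kramer post hoc tests and
    K-means/elbow cluster validation; a from-scratch NIPALS partial least
    squares (PLS1/PLS2) engine with leave-one-out Q2, component selection,
    variable importance in projection (VIP) and standardized coefficients;
    and the full block-wise modelling protocol (correlation pruning,
    climate/soil/physical matrix combinations, VIP prescreening, univariate
    per-type models, leave-N-out resampling summaries). A calibrated
    synthetic stream-site generator makes every stage testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    jsonlite
Config/testthat/edition: 3
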