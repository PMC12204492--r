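Package: avoidpop
Title: Population Coding Analyses for Signaled Active Avoidance Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-cell calcium imaging, fiber photometry
    and rabies-tracing data recorded during two-way signaled active avoidance.
    Implements trace preprocessing (neuropil subtraction, sliding-percentile
    dF/F, session z-scoring, isosbestic correction), auROC task-modulation
    classification against circular-permutation nulls, trial-averaged
    population PCA with Mahalanobis trajectory divergence and coding-direction
    projections, pseudo-population linear-SVM outcome decoding with shuffle
    nulls, functional k-means clustering with anatomical concentration tests,
    kernel-convolved GLM encoding models with nested predictor contributions,
    and input-proportion statistics for monosynaptic tracing, together with a
    synthetic session generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
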