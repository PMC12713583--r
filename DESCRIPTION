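Package: spikechoice
Title: Spike-Train Analysis of Value-Guided Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for analysing single-neuron spike trains
    recorded during a value-guided saccadic choice task: event-aligned
    spike-density estimation with baseline z-transformation, k-means
    classification of neurons into functional clusters with repeated
    silhouette-based selection of the cluster number, validation of the
    groupings by principal component analysis on stacked condition
    responses, mixed-effects models of condition effects and of the
    trial-by-trial link between neuronal response onset latency and
    saccadic reaction time, sliding-window choice regression, population
    state-space trajectories with a divergence-time statistic, and
    population decoding of choice with an elastic net under nested,
    neuron-grouped cross-validation.  A synthetic spike-train generator
    with planted ground truth supports parameter-recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    cluster,
    lme4,
    lmerTest,
    emmeans,
    glmnet,
    Matrix,
    pROC,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
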