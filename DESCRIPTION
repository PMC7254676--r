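Package: calnet
Title: Calcium-Imaging Analysis of Neuronal Culture Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for fluorescence calcium-imaging recordings of
    dissociated neuronal cultures: ROI detection from time-averaged movies,
    baseline-corrected trace normalization, moment-based trace classification
    (neuron / glia / silent) with an adaptive-boosting ensemble, spike-train
    reconstruction by iterative kernel peeling, network-burst detection with a
    two-threshold (Schmitt) trigger, effective-connectivity inference with
    Generalized Transfer Entropy, and graph-topology summaries (global
    efficiency, Louvain communities, connector hubs). Includes a synthetic
    culture generator with presets calibrated to wild-type and Huntington's
    disease striatal and cortical culture statistics, so that every stage can
    be validated against planted ground truth, plus group-level statistics
    (Tukey-fence outlier exclusion, Student's t tests, mixed-design ANOVA with
    Bonferroni post hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    igraph,
    rpart,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
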