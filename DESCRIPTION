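Package: flavdecode
Title: Crossmodal Flavour Decoding and Representational Drift Analysis for
    Chemosensory fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying shared neural representations of taste and
    retronasal odour in block-design chemosensory fMRI. Provides a synthetic
    BOLD and beta-pattern generator with plantable crossmodal pattern overlap
    and run-wise representational drift, first-level GLM estimation (canonical
    HRF convolution, discrete-cosine high-pass basis, motion and spike
    confounds, framewise-displacement censoring, grand-mean scaling, global
    signal detrending), multivariate decoding with leave-one-run-out,
    crossmodal and cross-session partitions (linear support-vector
    classification with training-mean centring), searchlight mapping,
    hierarchical within-subject permutation inference with threshold-free
    cluster enhancement, voxelwise tuning-index overlap analysis, and run-wise
    representational-drift analysis via correlation-distance RDMs and linear
    mixed models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
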