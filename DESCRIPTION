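Package: corrisc
Title: Correlated Components Analysis and Intersubject Correlation for Multi-Subject EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the similarity of stimulus-evoked EEG activity
    across individuals watching the same naturalistic videos. Implements
    correlated components analysis (CorrCA): pooled between- and within-subject
    covariances, the generalized eigenproblem yielding maximally intersubject-
    correlated electrode projections, forward-model scalp maps, leave-one-out
    intersubject correlation (ISC) against a reference cohort, and time-resolved
    ISC in overlapping sliding windows. Includes an EEG preprocessing chain
    (band-pass filtering, bad-channel zeroing, ocular ICA, outlier zeroing,
    z-scoring), relative alpha-band power of component time courses, automatic
    movement annotation of video stimuli from pose-estimation keypoint tracks,
    a statistical battery for two-group comparisons with covariates (Welch t,
    ANCOVA with generalized eta-squared, rank correlations, signed-rank tests,
    mixed-model table assembly), and a synthetic-cohort generator with known
    ground truth so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
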