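Package: scnca
Title: Multiscale Analysis of Suprachiasmatic Nucleus Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for system-level analysis of large-scale calcium imaging of
    the suprachiasmatic nucleus (SCN). Provides a synthetic SCN data generator
    with planted multiscale ground truth (burst classes, dynamical states,
    circadian activity modes, hour-specific population signatures, concentric
    spatial modules with opposing amplitude and coupling gradients, and a slow
    traveling hyperactivity wave); fluorescence trace extraction with
    background subtraction and delta-F/F burst attributes; K-means burst
    classification with gap-statistic model selection and class-switching
    dynamics; time-delay embedding of traces into directed phase-space graphs
    with a graph-convolutional state classifier and 12-h high/low activity
    mode assignment; hourly time decoding by polling random neuron cohorts
    with a convolutional predictor, accuracy curves, feature-space embedding
    and integrated-gradients per-neuron contribution coefficients; contrastive
    time-series representation learning for functional neuron subtype
    discovery with robustness subsampling; module-level amplitude and maximal
    information coefficient statistics with module-specific time predictors;
    and phase-wave front detection on spatial intensity maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    MASS,
    mclust,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
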