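Package: microlux
Title: Single-Cell Analysis of Bacterial Quorum-Sensing Sender-Receiver
    Microcolonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for time-lapse microscopy of
    engineered Escherichia coli quorum-sensing microcolonies growing in
    single-layer microfluidic chemostats.  Provides an agent-based rod-cell
    colony simulator with Hill-type AHL induction of a stable fluorescent
    reporter, lognormal cell-to-cell rate variability, extrinsic noise and a
    late-inducing subpopulation; a synthetic microscopy renderer with ground
    truth; watershed-based cell segmentation with a hybrid background
    classifier and SVM region filtering; maximum-overlap lineage tracking
    with a fluorescence-jump correction heuristic; expression-rate estimation
    (alpha = dF/dt per unit cell mass) and Hill dose-response fitting;
    population statistics (lognormal fits, Gaussian-mixture subpopulation
    separation, CV^2 noise curves); and an ODE model of LuxI/AHL production
    by sender cells used to calibrate receiver bacteria as AHL bioreporters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    deSolve,
    e1071,
    grDevices,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    tools,
    utils
Suggests:
    fitdistrplus,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
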