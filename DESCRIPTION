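Package: layercal
Title: Layer-Embedding Analysis and Probability Calibration for 3D
    Fully Convolutional Segmentation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing what each layer of a dilated-convolution 3D
    fully convolutional network (FCN) has learned, and for using those probes
    to calibrate the network's output probabilities. Each hidden layer is
    decomposed into spatial information aggregation (neighborhood
    concatenation) and information synthesis (convolution, batch
    normalization, activation); a random-forest "embedding output" classifier
    is fitted on the per-voxel representations at every pre- and
    post-convolution stage, and an early-layer embedding output is used to
    down-weight overconfident voxels in the final probability map. Includes a
    compact 3D CNN engine (dilated convolutions, batch normalization, 3D
    dropout, Adam), a synthetic liver-phantom generator with class-dependent
    multi-channel contrast, Monte Carlo dropout, deep-ensemble and Platt
    scaling baselines, and reliability-diagram, average-calibration-error,
    AUC and Dice metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
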