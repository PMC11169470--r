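Package: ilvis
Title: Incrementally Learned Visualization of Longitudinal High-Dimensional Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Incrementally learns a parametric two-dimensional embedding of
    longitudinal high-dimensional data and traces per-timepoint medians into
    progression trajectories. Implements a self-organizing vector-quantization
    embedding with a weighted topology graph and a cross-entropy 2D layout that
    is fine-tuned (never reinitialized) as new data increments arrive, so that
    consecutive visualizations of an ongoing experiment remain comparable.
    Includes a simulator of nonlinear high-dimensional trajectories with
    controllable sampling gaps and noise, FFT featurization of multi-electrode
    array (MEA) recordings, a threshold-crossing spike detector, a surrogate
    MEA recording generator, and Euclidean distance metrics for ranking
    trajectory (dis)similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse
Config/testthat/edition: 3
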