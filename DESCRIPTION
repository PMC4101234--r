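Package: nactct
Title: Sparse-View CT Reconstruction with Split-Bregman Total Variation and
    Non-Aliasing Contourlet Regularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for sparse-view parallel-beam
    computed tomography. Provides a Shepp-Logan-type head phantom, Siddon ray
    tracing for the sparse system matrix, an interleaved view-angle schedule,
    Gaussian projection noise, and three iterative reconstruction algorithms:
    algebraic reconstruction (ART, Kaczmarz sweeps with a positivity
    constraint), ART with total-variation regularization, and a Split-Bregman
    scheme that couples total variation with a non-aliasing contourlet
    transform (a multiscale, multidirectional tight frame built from
    anti-aliasing pyramidal filter banks and directional frequency windows).
    Image quality is assessed with root-mean-square error and the universal
    quality index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
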