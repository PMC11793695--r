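Package: hicflow
Title: Optical-Flow Forecasting of Spatiotemporal Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forecasts future Hi-C contact maps from two observed timepoints
    using a dynamic multi-scale voxel flow network: optical-flow estimation
    with backward warping and mask fusion, a chain of multi-scale voxel flow
    blocks refined coarse-to-fine, and a routing module with straight-through
    Bernoulli gating that selects blocks at inference. Includes the full
    preprocessing pipeline (clip-and-normalize, diagonal 64x64 patching,
    stitching), an exponentially block-weighted training objective with l1,
    mean-squared-error or Laplacian-pyramid distances, Adam optimization with
    cosine-annealed learning rates and validation-weighted checkpoint
    selection, a patch-wise evaluation suite (random-walk graph concordance,
    Pearson correlation, PSNR, SSIM, interaction recovery rate, pairwise
    timestep-similarity matrices), and a synthetic spatiotemporal Hi-C
    generator with TAD drift and loop dynamics for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
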