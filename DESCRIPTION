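Package: phytoreg
Title: Feature-Point Registration of Multimodal Plant Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated registration of fluorescence (FLU) and visible-light
    (VIS) images of plant shoots from high-throughput phenotyping systems.
    Provides structural pre-processing (background masking, colour-edge
    transformation, bounding-box cropping), five native feature-point
    detectors (Harris, minimum-eigenvalue, FAST, determinant-of-Hessian
    blobs, MSER) with a combined-detector merge, gradient-histogram
    descriptor matching with ratio and uniqueness constraints, RANSAC
    affine estimation with admissibility validation, an evaluation
    framework (success rate, overlap ratio, full factorial benchmark
    grid), and a seed-deterministic synthetic FLU/VIS scene generator
    with known ground-truth transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
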