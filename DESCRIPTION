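Package: shearfuse
Title: Multimodal Medical Image Fusion with Shearlets, Sparse Coding and
    Pulse-Coupled Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses pairs of co-registered medical images (CT/MR, MR/MR,
    MR/PET-style) in the transform domain. Images are decomposed with a
    translation-invariant, fully frequency-domain discrete shearlet
    transform; the low-frequency bands are fused by K-SVD dictionary
    learning and orthogonal matching pursuit sparse coding with an
    L1-norm three-case selection rule; the directional high-frequency
    bands are fused by a simplified pulse-coupled neural network whose
    link strength is the local spatial-frequency map, selecting
    coefficients by ignition counts. Includes the standard fusion
    quality metrics (spatial frequency, average gradient, mutual
    information, edge-preservation QAB/F), a seeded synthetic phantom
    generator for co-registered multimodal pairs, and a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
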