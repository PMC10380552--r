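Package: leaftrace
Title: Few-Shot Leaf and Vein Segmentation and Trait Extraction from Leaf Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Few-shot convolutional segmentation of whole-leaf scans: an
    iterative boundary-tracing network for the leaf body, a recursive
    region-growing network for the visible vein architecture, and a tiled
    U-Net baseline, together with the downstream phenotyping steps --
    morphological, venation and petiole trait extraction in physical units,
    segmentation evaluation (Jaccard, recall, connected components, Tukey
    grouping), caliper-style linear validation, and broad-sense heritability
    from clonal replicates. Includes a seedable synthetic leaf-scan generator
    with exact ground-truth masks so the full pipeline can be trained and
    evaluated end-to-end without external data. The convolutional engine
    (3x3 convolutions, batch normalization, leaky ReLU, residual blocks,
    max pooling, transposed-convolution decoder, Adam) is implemented in
    compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    multcomp,
    generics,
    stats,
    grDevices,
    utils,
    withr,
    jsonlite,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
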