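Package: hsiseg
Title: Dual-Branch Lightweight U-Net Segmentation of Hyperspectral Vegetation Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pixel-wise vegetation classification of hyperspectral imagery with a
    lightweight encoder-decoder network. Raw reflectance cubes are reduced to six
    principal-component channels; a second six-channel input stacks hand-crafted
    features (NDVI, four gray-level co-occurrence texture maps, Sobel edge
    magnitude). Both feed a U-Net whose convolutions are replaced by residual
    depthwise-separable feature-extraction modules with h-swish activations,
    fused per level into a shared decoder. Includes a synthetic labelled-scene
    generator for end-to-end testing, ENVI raster input/output, a per-class
    binary cross-entropy training loop with Adam, confusion-matrix metrics with
    two-level class grouping, and desk-scale ablation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    png,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
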