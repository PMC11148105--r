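Package: madrnet
Title: Multi-Level Attention Dilated Residual Networks for Medical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds and trains MADR-Net, a U-Net-shaped encoder-decoder for
    2-D biomedical image segmentation whose convolution blocks are
    multi-dilated residual blocks (parallel atrous branches at rates 1, 3, 5
    and 11 with a residual path), whose bottleneck and head are atrous
    spatial pyramid pooling (ASPP) blocks, and whose skip connections are
    gated by a channel-spatial attention module. Includes the hybrid
    training loss (cross-entropy + dice + focal Tversky), confusion-count
    segmentation metrics (dice, Jaccard, accuracy, precision, recall), a
    seeded generator of synthetic binary and multi-class segmentation
    fixtures, reverse-mode automatic differentiation with an Adam
    optimizer, and a train/evaluate/predict command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    tidyr,
    withr
Config/testthat/edition: 3
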