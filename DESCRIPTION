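Package: ripplepond
Title: Ripple Pond Networks: Rotation- and Scale-Tolerant Temporal Coding of Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ripple pond networks (RPNs): feed-forward spiking
    networks of unit-delay binary relay neurons arranged on a spiral disc
    that convert centered two-dimensional images into one-dimensional
    temporal patterns suitable for temporal-coding memory networks.
    Provides the max-min spiral neuron placement search, difference-of-
    Gaussians and rotation-equivariant radial Gabor feature maps, the
    inward ripple propagation with its summing and inhibitory (shutter)
    neurons, multi-channel multi-density disc banks, time-warp
    normalization of temporal patterns, and rotation/scale/translation
    invariance sweeps with cosine and Spearman similarity metrics.
    A procedural generator of centered test images (glyphs, words,
    shapes, blobs, silhouettes) makes every experiment reproducible
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
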