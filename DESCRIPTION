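Package: spatialcoherence
Title: Topology-Based Spatial Coherence Metrics for DNA Barcode Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial coherence of spatially embedded graphs,
    such as the DNA barcode networks produced by sequencing-based microscopy,
    using network topology alone. Provides three ground-truth-free
    diagnostics: the intrinsic network dimension from breadth-first-search
    ball scaling, a dimensionless spatial constant relating mean shortest-path
    distance to network size, and spectral scores (variance contribution and
    spectral gap) of the double-centered shortest-path Gram matrix. Includes
    synthetic spatial-network generators with known ground truth
    (k-nearest-neighbour, bipartite, diffusion-decay and Swiss-roll
    connectivity, and a polony diffusion weight model), controlled false- and
    missing-edge perturbations, and coherence-driven edge filtering via
    indirect-path confidence scores and golden-section threshold
    optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
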