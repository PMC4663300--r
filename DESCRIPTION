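Package: hafsaseg
Title: Hybrid Artificial Fish Swarm and Fuzzy C-Means Grayscale Image
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Grayscale image segmentation by fuzzy c-means (FCM) clustering
    with cluster centers optimized by an artificial fish swarm metaheuristic
    (prey, swarm, follow and random behaviors) hybridized with a Metropolis
    acceptance rule under a geometric cooling schedule and an in-loop
    neighborhood-based noise reduction mechanism. Includes plain FCM and
    suppressed-FCM baselines, cluster-validity and segmentation-quality
    metrics (objective value, PSNR, MSE, partition coefficient and entropy,
    accuracy, Jaccard similarity), a synthetic grid-graph benchmark generator
    with Gaussian, speckle and salt-and-pepper noise injectors, PGM/PNG image
    input and output, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
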