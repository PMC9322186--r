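Package: hcwssc
Title: Hybrid Changing-Weight Spectral Similarity Clustering for Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Unsupervised land-cover and crop mapping from hyperspectral images
    with a hybrid-kernel K-means classifier. Four spectral dissimilarity
    measures (Euclidean distance, spectral angle cosine, spectral correlation,
    spectral information divergence) are computed as per-pixel feature maps
    against the scene mean spectrum; a filter feature selection picks the two
    least Pearson-correlated measures and weights them by their coefficients
    of variation divided by the map means, yielding a dimensionless weighted
    hybrid kernel for K-means. Includes single-kernel and unweighted-hybrid
    baselines, elbow-method cluster-count diagnostics, a triplet-library
    classification protocol, confusion-matrix evaluation (overall accuracy,
    Cohen's kappa, per-class F1), synthetic scene and spectral-library
    generators, ENVI/TIFF raster and delimited-text library I/O, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
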