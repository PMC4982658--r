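Package: facomp
Title: Compositional Noise Analysis of Multiplexed Focal Adhesion Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring changes in compositional noise within
    focal adhesions from multiplexed single-adhesion protein densities.
    Provides a stochastic binomial simulator of adhesion-site assembly
    with tunable diversity and binding noise, a synthetic-data generator
    for multiplexed image stacks and density tables, an image-analysis
    chain (subpixel registration, high-pass background subtraction,
    watershed segmentation, backward tracking, age and dynamics
    classification), Box-Cox/Tukey/Otsu preprocessing, the
    delta-log(CV) / delta-r-squared noise-versus-diversity inference
    statistic, and a neural-network / Random-Forest subset screen with
    an F-test-directed subset-lattice DAG for detecting high-order
    compositional relations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    igraph,
    randomForest,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
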