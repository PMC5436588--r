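Package: forestscape
Title: Spatio-Temporal Analysis of Natural Forest Cover Change on Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based analysis of natural forest cover (NFC) change and its
    association with road-network expansion. Builds a regular cell lattice over a
    land mask, derives per-cell NFC from forest maps and terrain/productivity
    covariates from rasters, computes four road-network indicators (road length
    density, distance to nearest road, node density, mean node degree) per road
    class and period, hindcasts historical NFC with pluggable regression backends
    selected by normalised mean square error, quantifies change rates and the
    explanatory power of each indicator with variation partitioning, and detects
    hot and cold spots of change with the Getis-Ord Gi* statistic. Includes a
    fully synthetic island generator so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    randomForest,
    mgcv,
    nnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
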