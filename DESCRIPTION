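Package: fconn
Title: Functional Connectome Construction and Graph-Theoretical Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted functional brain networks from region-of-interest
    (ROI) time series via Pearson correlation, applies density-based edge
    thresholding, nodal elimination, and group averaging, and computes
    weighted graph metrics (degree, strength, Onnela clustering, global
    efficiency, small-world index) normalized against degree- and
    weight-preserving null ensembles. Community structure is estimated by
    Kernighan-Lin-style modularity refinement with consensus over repeated
    seeded runs, partitions are compared by normalized mutual information,
    and hubs are classified into connector and provincial roles by their
    participation coefficients. Paired condition contrasts use max-statistic
    permutation tests with family-wise error control. A synthetic-data
    module generates multi-subject ROI panels with planted modular
    structure, hubs, and condition effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
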