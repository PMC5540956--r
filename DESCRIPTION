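Package: perconet
Title: Percolation-Based Sparsification Thresholds for Community Detection
    in Weighted Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to select the sparsification threshold of a weighted
    (brain-like) functional connectivity network by percolation analysis:
    the highest edge-weight threshold that keeps the giant connected
    component intact. Includes a weighted Lancichinetti-Fortunato-Radicchi
    (LFR) benchmark generator with planted community structure, a
    Cholesky-based multi-subject fMRI time-series simulator with Rician
    noise, Pearson/Fisher group connectivity construction, three community
    detection methods (Newman modularity via Louvain, Asymptotical Surprise
    via a PACO-style agglomerative optimizer, and InfoMap), and ground-truth
    evaluation via normalized mutual information, sensitivity and
    specificity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
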