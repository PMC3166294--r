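Package: prioNet
Title: Disease-Gene Prioritization by Coupled Heterogeneous Network Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease-causing genes by propagating known
    disease-gene associations over two coupled networks: a phenotype
    similarity network over diseases and a self-loop-extended protein-protein
    interaction network over genes. Scores are computed by an iterative
    bilinear update that mixes a similarity-derived prior with the
    network-smoothed term and stops on a mean-square-deviation criterion.
    Includes the matching evaluation protocol (k-fold cross-validation with
    random, genome-wide and linkage-interval control sets, precision/recall
    at rank cutoffs, Gaussian-noise robustness), local disease-subnetwork
    discovery by approximate personalized PageRank with a conductance sweep
    (PageRankNibble), and a generator of modular synthetic benchmark
    instances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
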