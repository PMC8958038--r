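Package: proxtalk
Title: Network-Based Drug Repurposing with Proximity and Crosstalk Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores drug-disease and drug-drug associations on a functional
    association network using four null-model-normalized statistics: shortest
    path proximity with a degree-aware permutation null, and three network
    crosstalk tests (a hypergeometric link model, a binomial model calibrated
    by degree-preserving network randomization, and a beta-binomial model
    fitted to degree-matched set samples). Includes benchmark construction
    from labeled drug-disease tables with overlap filtering and time-stamped
    relabeling, classifier-style evaluation (ROC/AUROC, PR/AUPR, balanced
    resampling, threshold selection, recall), and a synthetic-data generator
    that plants association signal on scale-free networks so the whole
    pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
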