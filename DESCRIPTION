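Package: rnadecoy
Title: Detection of Non-Homologous Contaminants in Sets of Putative RNA Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for flagging contaminant ("decoy") sequences in small sets
    of putative homologous structured RNAs. A simplified iterative
    consensus-folding engine estimates base-pair probabilities by partition
    function calculations, refines them with extrinsic information shared
    across the group through pair hidden Markov model alignment posteriors,
    and builds a progressive multiple alignment. Six per-sequence features
    (a Kullback-Leibler score over pairing/unpairing-status histograms, a
    folding free energy Z-score, mean sequence Shannon entropy, and
    structural Shannon entropies before and after consensus refinement plus
    their difference) feed an adaptive-boosting classifier that reports the
    probability each sequence is a decoy. Includes shuffled and cross-family
    decoy generators, a synthetic family simulator for training and
    benchmarking, ROC/AUC evaluation, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
SystemRequirements: C++17
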