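Package: tcsmeta
Title: Meta-Prediction of Two-Component System Histidine Kinase-Response
    Regulator Pairings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate histidine kinase (HK) / response regulator (RR)
    pairings in prokaryotic two-component signalling systems by computing six
    sequence- and genome-context-based interaction features (in-silico
    two-hybrid correlated mutations, mirror-tree coevolution, gene fusion,
    phylogenetic profiling with mutual information, gene neighbourhood, gene
    operon) and fusing them with a class-weighted RBF-kernel support vector
    machine. Includes the full benchmarking stack (stratified k-fold cross
    validation, sensitivity/specificity/accuracy/MCC, ROC and AUC, paired
    DeLong ROC comparison) and seeded synthetic-data generators (co-evolving
    alignments, reference genomes with planted fusion/neighbour/operon/profile
    events, imbalanced feature tables) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    e1071,
    Biostrings,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ape,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
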