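Package: graphvir
Title: Graph-Based Identification of Viral Sequences in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies viral contigs in metagenome assemblies by representing
    each nucleotide sequence as a multilayer graph (900 bp segments, 90-mers,
    9-mers and single bases linked by hierarchy, local and segment edges),
    embedding the nodes with a cascade of graph convolutional networks trained
    level by level, and classifying the whole graph with multi-head graph
    self-attention using relative positional coding. Includes a two-class
    Markov-chain sequence simulator with optional planted motifs so the full
    pipeline can be trained and evaluated without external downloads, plus
    standard binary-classifier evaluation (accuracy, recall, precision,
    specificity, F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
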