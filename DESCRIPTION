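Package: molmiR
Title: Small Molecule-miRNA Association Prediction with Graph and
    Sequence Neural Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts associations between small molecule drugs and
    miRNAs from molecular structure and sequence alone. Molecules are
    parsed from SMILES into heavy-atom graphs, atoms and bonds are typed
    by canonical r-radius neighborhood fingerprints, and a graph neural
    network with learned fingerprint embeddings encodes each molecule.
    miRNA sequences are tokenized into overlapping 3-mers and encoded by
    a convolutional filter stack over embedded k-mer windows. A neural
    attention mechanism couples the two encoders, scoring each sequence
    window against the molecule embedding, and a softmax head outputs
    association probabilities. Includes negative sampling, pairwise
    k-fold and leave-one-molecule-out cross-validation, ROC/AUC,
    candidate ranking, and a planted-signal synthetic data generator so
    the whole pipeline can be exercised offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
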