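Package: seq2mol
Title: Protein-Conditioned Molecule Generation and Binding Affinity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, offline-testable drug-discovery pipeline: preprocessing
    of ligand-protein affinity tables (Ki to pKi transform, length and affinity
    filters, reproducible train/validation splits), byte-pair-encoding and
    character-level tokenization of paired SMILES and amino-acid sequences, a
    decoder-only transformer chemical language model that generates candidate
    small molecules conditioned on a protein sequence, an iterative end-trimming
    repair that shortens raw generations to syntactically valid SMILES, a
    one-dimensional convolutional regression network that predicts pKi from
    character-encoded ligand-protein pairs, generation quality metrics
    (validity, uniqueness, internal diversity, QED), and an orchestration layer
    that threads a user query through literature retrieval, target extraction,
    sequence lookup, generation, repair, and affinity prediction over pluggable
    providers. A synthetic fixture generator with a known, learnable affinity
    function makes every stage testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with the rdkit package, available on the
    PATH as 'python' (used for SMILES parsing, canonicalization, fingerprints
    and QED through a batched subprocess bridge).
Config/testthat/edition: 3
RoxygenNote: 7.3.3
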