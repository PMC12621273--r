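Package: ppigat
Title: Protein-Protein Interaction Prediction with Residue Contact Graphs and Graph Attention Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether two protein chains interact from their
    structures. Each chain pair is turned into a residue-level graph
    (intra-chain edges below an 8 Angstrom C-alpha cutoff weighted by
    distance, fully connected inter-chain edges at fixed weight 8), node
    features come from pluggable per-residue embedders (one-hot baseline,
    deterministic synthetic embedder, or externally computed language-model
    matrices), and a four-layer multi-head graph-attention classifier with
    chain mean pooling outputs an interaction probability. Also provides
    the pDockQ interface-scoring baseline, dataset filtering and balanced
    negative sampling, rank-based evaluation metrics, attention-weight
    export, and a synthetic two-chain complex generator for fully offline
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    yaml,
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
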