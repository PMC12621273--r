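# ppigat

Structure-based prediction of protein–protein interactions (PPI) with a
residue-level graph-attention classifier, plus the pDockQ structural
baseline — for computational structural biologists who want to score
whether two protein chains interact, given their (experimental or
predicted) structures.

## The method

Each chain pair is represented as one graph:

- **Nodes** are residues, with per-residue feature vectors from a pluggable
  embedder — a fully offline one-hot baseline occupying the first 21 slots
  of an *L*-dimensional vector, a deterministic synthetic embedder for
  testing, or externally computed protein language-model matrices loaded
  from TSV.
- **Intra-chain edges** connect residue pairs whose Cα–Cα distance is
  strictly below 8 Å, weighted by that distance. A sequence-only mode
  (`graph_mode = "esm2ac"`) instead takes edges from predicted
  contact-probability matrices (probability > 0.5, weight 8).
- **Inter-chain edges** fully connect the two chains at fixed weight 8 Å,
  giving cross-chain message passing whose strength is learned by
  attention rather than encoded in the graph.

Four graph-attention (GAT) layers with hidden dimensions
[L/2, L/4, L/2, L] update the node features. Per head, the attention
coefficient of node *i* over neighbour *j* is

    α_ij = softmax_{j ∈ N(i)} LeakyReLU(aᵀ [W h_i ‖ W h_j ‖ w_ij / 8])

with four heads averaged at every layer, batch normalisation plus ELU
between layers, and self-loops added inside the layer. The final node
features are concatenated with the input embeddings, **chain mean pooling**
(global mean per chain, then concatenation) produces a 4L graph feature,
and a fully connected layer with a sigmoid outputs the interaction
probability. Training uses binary cross-entropy, Adam at learning rate
1e-4, batch size 8 with gradient accumulation over 4 batches (effective
batch 32), for 10 epochs. The forward and backward passes are implemented
in vectorised base R with sparse aggregation operators.

The package also implements the pDockQ baseline

    pDockQ = 0.724 / (1 + exp(-0.052 (x - 152.611))) + 0.018,
    x = if_pLDDT · ln(n_contacts)

where `if_pLDDT` is the mean pLDDT over interface residues (read from the
PDB B-factor column) and `n_contacts` the number of contacted residues at
the same 8 Å Cα cutoff; the conventional decision threshold is 0.23.

Supporting modules cover PDB chain I/O, the dataset rules (positive pairs
need more than eight inter-chain contact pairs and chain lengths within
35–300; negatives are balanced uniform draws excluding known interactions),
rank-based evaluation metrics (accuracy, precision, recall, F1, AP, AUROC),
per-layer/per-head attention-weight export, and a synthetic complex
generator that plants both a geometric signal (posed interfaces vs
separated chains) and a sequence signal (basic K/R/H residues facing acidic
D/E) so the whole pipeline is testable offline.

## Worked example

```r
library(ppigat)

dir <- file.path(tempdir(), "toy_ppi")
man <- generate_dataset(10, 10, dir, seed = 42)   # 20 labeled complexes
fit <- ppi_gat(man, dim_L = 32,
               control = train_config(epochs = 2, batch_size = 4,
                                      accumulation_steps = 1),
               seed = 1)
summary(fit)
```

```
Graph-attention interaction classifier
  20 pairs (10 positive), embedder 'onehot', dim_L = 32
  hidden dims [16, 8, 16, 32], 4 heads, edge weights 'append'
  10 optimizer updates, final loss 0.6923

Training-set performance:
Binary classification metrics (threshold 0.5 )
  accuracy  0.900
  precision 0.833
  recall    1.000
  F1        0.909
  AP        0.973
  AUROC     0.970
  confusion TP=10 FP=2 FN=0 TN=8
```

After only ten optimizer updates the raw probabilities still sit near 0.5
(`predict(fit, man[1:2, ])` prints `0.5002 0.5000`) but their ranking
already separates the classes, which is what the threshold-free AP/AUROC
measure. The structural baseline on the first (interacting) pair:

```r
a <- read_chains(man$pathA[1])[[1]]
b <- read_chains(man$pathB[1])[[1]]
interface_summary(a, b)
#> pDockQ 0.742  (n_contacts = 40, if_plddt = 83.3)
```

A zero-contact pair returns the analytic floor `pDockQ 0.018`.

`predict(fit, newdata)`, `coef()`, `plot()` (loss curve), `residuals()` and
`simulate()` complete the modelling interface; `ppi_cli()` (or the
`inst/scripts/ppigat` wrapper) exposes `predict`, `train`, `eval`,
`pdockq`, `make-synth`, `filter-pairs` and `sample-negatives` subcommands
for shell use.

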