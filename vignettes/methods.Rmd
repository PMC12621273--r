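---
title: "Residue-graph attention for protein–protein interaction prediction: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-graph attention for protein-protein interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppigat)
```

## The prediction problem

Given the structures of two protein chains, does the pair physically
interact? `ppigat` answers this with a residue-level graph classifier: it is
aimed at the setting where structures (experimental, or predicted by
AlphaFold-style tools that write per-residue pLDDT confidence into the PDB
B-factor column) are available or can be predicted, and large panels of
candidate pairs need scoring.

## Graph representation

Each chain pair becomes one graph. Residues are nodes; their features come
from an embedder. Within a chain, an edge connects every residue pair whose
Cα–Cα distance is strictly below 8 Å, and the edge weight is that distance.
Between the chains every residue pair is connected by an artificial
("fictional") edge of fixed weight 8 Å. These dense inter-chain edges are
deliberately label-independent: positives and negatives get exactly the same
inter-chain topology, so any discrimination must come from what the
attention mechanism learns about the node features, not from the graph
wiring. Both cutoffs are strict inequalities (d < 8 Å for contacts,
probability > 0.5 in the contact-map mode); residues exactly at a boundary
are excluded, and the tests pin this behaviour.

A sequence-only variant (`graph_mode = "esm2ac"`) replaces the
distance-derived intra-chain edges with edges between residue pairs whose
externally predicted contact probability exceeds 0.5, at the same fixed
weight 8. It reuses weights trained on structural graphs, so it serves as a
fast screen when structures are unavailable.

## Node features

Three providers implement one contract (a deterministic map from sequence to
an N × L matrix):

- `onehot`: residue identity in the first 21 columns (20 standard amino
  acids alphabetically, then the unknown code X), zero-padded to `dim_L`.
  The padding exists because the architecture ties its hidden dimensions to
  L, which for real protein language models is 1024–1280; tests use L = 32.
- `synthetic`: pseudo-random unit vectors keyed by (letter, seed) — a test
  double for language models with the same determinism guarantees.
- `file`: N × L matrices computed out of process (e.g. by ProtT5 or ESM-2)
  and loaded from TSV with shape validation. The package never downloads or
  runs language models, and applies no normalisation to loaded embeddings.

## The classifier

Four graph-attention layers with hidden dimensions [L/2, L/4, L/2, L]
(a U-shape) and four heads each. Per head, the attention logit of node *i*
over neighbour *j* is `LeakyReLU(aᵀ[Wh_i ‖ Wh_j ‖ w_ij/8])`, softmax-
normalised over the in-neighbourhood of *i* (self-loops are added inside the
layer at the neutral weight 8, so every node attends to itself); head
outputs are averaged at every layer. Batch normalisation followed by an ELU
sits after layers 1–3. The final node features are concatenated with the
input embeddings, mean-pooled per chain, the two chain vectors concatenated
(dimension 4L), and a single affine map plus sigmoid yields the interaction
probability. Training minimises binary cross-entropy with Adam at learning
rate 1e-4 over 10 epochs, batch size 8, gradients accumulated over 4
batches (effective batch 32); updates per epoch are
`floor(n_batches / 4)`, with a trailing incomplete accumulation group
dropped rather than applied at a different effective batch size.

Choices the published description leaves open, and what this package does:

- **Edge weights in attention.** The attention formula has no edge term,
  yet the graphs carry weights. Default `edge_weight_mode = "append"`
  appends the scalar `w/8` to the concatenated features before the dot
  product with `a`; `"none"` reproduces the vanilla formula. Both modes are
  tested against a dense reference implementation.
- **LeakyReLU slope 0.2** (the GAT convention) and **ELU** as the
  inter-layer activation, both configurable.
- **Head combination is averaging at every layer including the last**,
  reading the stated averaging without exception (the original GAT paper
  concatenates except at the output layer).
- **Batch normalisation "between" layers** is read literally: after layers
  1–3, none after layer 4. Running statistics (momentum 0.1) are used in
  inference; batch statistics per graph in training.
- **Initialisation**: Glorot-uniform for the attention layers; the fully
  connected head starts at exactly zero, so the untrained model outputs
  probability 0.5 and early optimisation follows the loss gradient instead
  of head-initialisation noise. With only ~120 optimizer updates in the
  default recipe, a randomly initialised head would dominate the ranking
  for much of training; zero-initialising a final linear layer is standard
  practice and creates no symmetry problem because the layers behind it are
  random.
- **Decision threshold 0.5** with ties counted positive; the confusion
  matrix convention is documented because the original description does not
  state one.
- **Chain order matters** to pooling (A then B as given); an orientation-
  averaged prediction is easy to add by averaging `forward(A,B)` and
  `forward(B,A)` but is off by default.

The forward and backward passes are written in vectorised base R. Per-graph
edge structures (including sparse node-aggregation operators) are built once
and reused across layers, epochs and the backward pass; gradient
correctness for every parameter block is pinned by central-difference tests.

## pDockQ baseline

The structural baseline scores a complex as
`0.724 / (1 + exp(-0.052 (x - 152.611))) + 0.018` with
`x = if_pLDDT · ln(n_contacts)`. `n_contacts` counts contact *residues*
(the union over both chains; a pairs-counting flag exists for sensitivity
analysis) at the same Cα < 8 Å definition used everywhere else in the
package — the original FoldDock implementation used Cβ atoms, so absolute
scores on real structures can differ slightly. The logarithm is natural. A
zero-contact complex returns the analytic floor 0.018 rather than an error,
keeping rankings total; at n_contacts = 1 the score is independent of pLDDT
because ln 1 = 0 (the monotonicity tests therefore start at 2). The default
decision threshold is 0.23, with 0.21 noted as optimal on some data.

## Dataset rules

Positive pairs must have strictly more than eight inter-chain contact pairs
and both chain lengths within [35, 300] inclusive. "More than eight
contacts" is counted on residue *pairs* (the contact definition is stated
on pairs); a residues-counting mode is available because the original
pipeline's convention is not recoverable. Negative sampling enumerates all
admissible unordered pairs from the positive set's proteins — excluding
self-pairs, duplicates and an exclusion list of known or suspected
interactions — and samples without replacement, which is exactly uniform
and fails loudly (reporting the achievable maximum) when too many pairs are
requested. Balanced manifests carry all positives plus an equal number of
sampled negatives, shuffled under the seed.

## What the synthetic generator emulates — and what it does not

The generator builds two-chain complexes as self-avoiding random walks with
exact 3.8 Å consecutive-Cα spacing (the canonical backbone step) and a
2 Å clash floor. Its defaults are the package's study conditions, chosen
once:

- chain lengths drawn from 40–60 residues (small single-domain proteins;
  inside the 35–300 filter window),
- positives posed to at least 20 inter-chain contact pairs — a typical
  small dimer interface — giving roughly 10–15 contact residues per chain,
- interface residues of chain A drawn from {K, R, H} and of chain B from
  {D, E}, planting a charge-complementarity sequence signal that a one-hot
  embedder can exploit (inter-chain edges are label-independent, exactly as
  in real graphs, so node features must carry the signal),
- pLDDT regimes: interface mean 85, background 70, sd 8 for positives;
  uniform mean 65 for negatives; values clipped to [0, 100] — chosen so the
  pDockQ baseline ranks fixtures correctly and the two scoring routes can
  be compared,
- negatives translated apart to at least 12 Å everywhere (safely beyond
  the 8 Å cutoff), hence exactly zero contacts.

Labels are therefore recoverable from geometry alone — a non-learning
contact-count oracle reaches AUROC 1.0, an upper bound that the learned
model is *not* expected to reach from sequence composition at 120 optimizer
updates. What passing tests show is that the pipeline is correctly wired
and the optimisation learns a planted, learnable signal under the published
recipe; they do not show real-data performance. Real interfaces have
partial contact overlap between positives and negatives, no clean
charge-complementarity rule, structural noise in predicted models, and
sequence redundancy between splits — none of which the generator emulates.

## Problem sizes and numerics

The test and acceptance runs use 400 training pairs and 100 held-out pairs
at L = 32 with one-hot features — a scale at which a full training run
takes a few minutes on one CPU; the learnability check is run over three
training seeds with a majority verdict (stopping early once the majority is
decided) because 120 Adam updates leave genuine run-to-run variance.
Attention softmaxes subtract per-neighbourhood maxima before
exponentiation; probabilities are clamped to [1e-12, 1 − 1e-12] inside the
loss; batch-norm uses eps 1e-5. Degenerate inputs are defined rather than
accidental: an isolated node attends only to its self-loop; a single-class
evaluation reports AP/AUROC as undefined (never 0); zero predicted
positives report precision 0 with an explicit flag so F1 stays defined.

## Known limitations

- Real-data performance claims are out of scope: no language-model
  inference, no external interaction databases, no pretrained weights.
- The esm2ac mode is only as good as the supplied contact maps; with maps
  thresholded from true distances it reproduces structure-mode predictions
  closely (tested at tolerance 0.05), but real predicted maps will differ.
- Training is single-threaded and CPU-bound; the implementation is sized
  for hundreds of pairs with chains of tens to hundreds of residues, not
  for million-pair corpora.
- Only Cα-based geometry is used everywhere; all-atom or Cβ contact
  definitions are not implemented (only flagged for pDockQ).
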