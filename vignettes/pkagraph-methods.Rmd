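---
title: "Methods: residue-graph pKa regression in pkagraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-graph pKa regression in pkagraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pkagraph` predicts the pKa of an ionizable residue (Asp, Glu, His,
Lys) from a graph built over that residue's own atoms. The environment
— everything the graph does not contain as nodes — enters exclusively
through node features: heavy-atom neighbour counts, hydrogen-bond
counts and solvent accessibility. This is a deliberate asymmetry: the
covalent topology of the residue is fixed chemistry and carries the
message-passing structure, while the variable microenvironment is
summarized into per-atom descriptors. The practical consequence is
that all graphs of one residue type are isomorphic and the regressors
must extract everything discriminative from the features; tests that
permute node order or rigidly move the structure therefore pin down
the two invariances the representation promises (permutation and
rigid-motion invariance).

### Local coordinate frame

The frame is built from three anchors of the target residue only: Cα
(origin), carbonyl C and carbonyl O. X is the unit Cα→C vector, Z is
`unit(e_x × unit(O − C))` and Y completes the right-handed system.
Using only the residue's own carbonyl group (rather than atoms of the
next residue, whose coplanarity is the physical motivation but not a
construction requirement) keeps the frame computable next to chain
termini. The Z sign convention places the carbonyl O at positive local
Y, so ideal geometry lands the carbonyl C at (1.53, 0, 0) and O near
(2.16, 1.05, 0) with its Z exactly zero. Degenerate anchors (|Cα−C| ≤
0.5 Å, or O within sin⁻¹(10⁻⁶) of the Cα–C line) are rejected as
errors rather than repaired.

Dipole vectors are rotated into the frame (no origin shift). The
alternative — leaving them in the global axes — would silently break
rotation invariance of feature slots 8–10, which is the entire point
of the frame; this was a genuinely open choice and the invariant
settled it.

### Features and normalization

Slots 1–4 and 18–26 are one-hot blocks and each sums to exactly 1 per
node. Coordinates (Å), dipoles (Debye) and SASA (Å²) keep their
physical scales — batch normalization is intentionally absent so
absolute geometry and electrostatics survive into the model — while
neighbour counts and hydrogen-bond counts (slots 11–16) are min–max
scaled to [0, 1] with dataset-wide constants that are stored and
replayed at inference (`apply_normalization()`). A constant slot maps
to 0, avoiding division by zero and keeping zero counts sparse. The
neighbour-count block has four slots (C, N, O, S) computed at one
radius per dataset variant, defaulting to the crop radius; a
per-radius expansion would not fit the fixed 26-slot schema.

### Environment descriptors

*Neighbour counts* are closed-ball counts of context atoms (atoms of
other residues inside the crop sphere) around each target atom;
hydrogens never count.

*Hydrogen bonds* use a geometric Baker–Hubbard-style test: H···acceptor
≤ 2.5 Å and donor–H–acceptor angle ≥ 120°, donors/acceptors restricted
to N and O, intra-residue pairs excluded. Both thresholds are
arguments. A hydrogen's covalent donor is its explicit bond partner
when connectivity is known, else the nearest heavy atom *of its own
residue* within 1.2 Å — the residue restriction matters: a strongly
hydrogen-bonded H can sit closer to the acceptor than to its own donor,
and a cross-residue nearest-atom rule would misassign it.

*SASA* is Shrake–Rupley with a deterministic golden-spiral point set
(default 960 points, probe 1.4 Å, vdW radii C 1.70 / N 1.55 / O 1.52 /
S 1.80 / H 1.20 Å), computed on the **full** structure and read off for
target atoms — cropping first would fabricate exposed surface at the
sphere boundary. One subtlety: a quadrature grid fixed in space is not
rotation-invariant (the occlusion pattern changes as the molecule
turns under the grid), so each atom's grid is oriented by a frame built
from its two nearest occluding neighbours (distances rounded to 10⁻⁶ Å
before ordering, serial as tie-break, a Householder-style fallback for
collinear occluders). The grid then co-rotates with the molecule and
per-atom areas are exactly reproducible under rigid motion, which the
invariance suite checks at 10⁻⁸.

### The three regressors

All are three-stage (input → single hidden layer → output), written
from their update equations with hand-derived gradients; the test
suite validates every layer against a literal dense evaluation of its
equation and every gradient against central finite differences
(tolerance 10⁻⁶).

* **GCN**: symmetric-normalized aggregation over closed neighbourhoods;
  the degree convention counts the self-loop, matching the adjacency's
  unit diagonal. ReLU after the hidden layer; the output layer is
  linear (a regression head must reach pKa values above 12 and shifted
  values below 0), node scores are mean-pooled.
* **GIN**: open-neighbourhood sum plus `(1+ε)`-weighted self term, ε
  initialized at 0 and learnable; the MLP is linear–ReLU–linear with
  both widths equal to `hidden_channels`; pooling (mean/add) is a
  tunable, followed by a linear readout.
* **GATv2**: per-head scores `aᵀ LeakyReLU(W_s h_i + W_t h_j)`
  (negative slope 0.2), softmax over the closed neighbourhood with
  max-subtraction for overflow safety; the self term uses the source
  transform `W_s h_i`. Heads concatenate; a second single-head
  attention layer to width 1 followed by mean pooling mirrors the GCN
  output pattern — the head/pool ordering of the output stage was an
  open choice and this keeps the three architectures structurally
  parallel.

Weight initialization is Glorot-uniform seeded from
`model_config(seed=)`; the same seed also drives epoch shuffling and
dropout masks, so any run is bit-reproducible. Dropout (inverted
scaling) applies only to the hidden representation and only in
training mode; evaluation is deterministic.

### Training, cross-validation, metrics

Adam (β₁ 0.9, β₂ 0.999, ε 10⁻⁸) over minibatches assembled as
block-diagonal edge-list batches. Early stopping monitors the
validation loss of the configured kind with patience 20 and restores
the best epoch's weights; `max_epochs` defaults to 500. Each CV fold
trains with the held-out fold as its early-stopping monitor and
contributes that fold's predictions to the pool, so every graph is
predicted exactly once and pooled MAE/RMSE mirror a
validation-batch-collection protocol. Fold membership is a seeded
random near-equal partition; residue-type stratification is available
but off by default.

The evaluation suite reports overall and per-type MAE/RMSE, the
quantile segmentation of |experimental shift| with left-closed
intervals at cut points 0.2/0.5/1.0 (the last interval open above, so
nothing is dropped), last/first-segment error ratios, the
reference-value null model (Asp 3.7, Glu 4.2, His 6.5, Lys 10.4), and
the Pearson correlation of predicted vs experimental shifts — the
metric least flattered by datasets whose labels cluster near the
references.

Learning-rate grids accept arbitrary lists; published grids for this
family of models are inconsistent between tuning ranges and reported
best models, so no single list is hard-coded.

### Explainer

Feature and edge masks are sigmoids of learnable logits (so they stay
in [0, 1] at every step), the feature mask shared across nodes (26
values). The objective is
`(f(A∘M_e, X∘M_f) − f(A, X))² + λ₁·mean(M_f) + λ₂·Σ entropy(M)` with
λ₁ = 0.05, λ₂ = 0.01, 200 Adam steps (lr 0.1), early exit when the
objective moves < 10⁻⁶. The squared deviation of the masked from the
unmasked prediction is the regression surrogate for the
conditional-entropy term of the mutual-information objective, which is
classification-oriented in its original form. Edge masks are shared
between the two directions of a bond and multiply messages
post-normalization in every layer. Logits initialize at N(−0.5, 0.1)
(mask ≈ 0.38): starting above mask ≈ 0.55 would let the entropy
penalty's pull toward 1 overpower the per-slot size penalty
(λ₁/26 ≈ 0.002) on inputs the model never reads, which is visible as
spurious top-ranked slots. Aggregation across graphs is the mean mask
rescaled by its maximum slot.

## The synthetic generator

`make_ideal_residue()` builds residues from ideal stereochemistry
(Cα–C 1.53 Å, C=O 1.23 Å, Cα–C–O 121°, internal-coordinate placement
for side chains and hydrogens); `make_toy_protein()` chains them with
trans peptide bonds (C–N 1.33 Å, ω = 180°) along a gently meandering
extended backbone (φ ≈ −120° ± 12°, ψ ≈ 130° ± 12°, giving Cα–Cα ≈
3.8 Å), interleaving GLY/ALA spacers so neighbour-count features are
non-trivial. Dipoles are seeded isotropic zero-mean vectors with
per-component scale 0.3 D — the magnitude regime of induced dipoles
under a polarizable force field. Labels are
`reference(type) + β·mean-pooled features + N(0, σ)` with a sparse β
touching local-frame coordinates, the dipole x component, C/O
neighbour counts, the acceptor count and SASA, spreading the
deterministic part over a few pKa units.

What passing on these fixtures shows: the representation's invariances,
the optimizer's ability to recover a planted feature→label mechanism
through each architecture, and the correctness of every metric and the
explainer against ground truth. What it does not show: performance on
real structures — the fixtures have no rotamer diversity, no ligands,
no charge-charge networks, and their label mechanism is linear in
pooled features, far simpler than real pKa physics. The planted
mechanism also produces mostly large positive shifts (the count and
SASA features are strictly positive), so the quantile segmentation is
only exercised meaningfully by the constructed metric tests, not by
the recovery experiment.

## Problem sizes and numerical choices

The parameter-recovery experiment uses 400 graphs (40 proteins × 10
ionizable residues, radius 9 Å), σ = 0.3, and a fixed config per
architecture: hidden 64, lr 0.01, batch 32, dropout 0, MSE loss,
max 300 epochs, patience 20, 4 heads (GAT), mean pooling; 10-fold CV
pooled MAE lands near 0.25 — essentially the σ = 0.3 noise floor
(E|N(0, σ)| ≈ 0.24) — for all three architectures, and is monotone in
σ over {0, 0.3, 0.6}. Dropout is off in this experiment because the
planted mechanism is noiseless apart from the label noise and the
point is recovery, not regularization. These sizes keep the full
recovery suite at roughly eight minutes on one CPU core.

Other constants: frame orthonormality asserted to 10⁻⁹; isometry of
`to_local` to 10⁻⁹; layer-vs-dense-equation agreement to 10⁻⁶ over 50
random parameter draws on graphs of up to 6 nodes; SASA quadrature 960
points (0.5 % accuracy on the isolated-sphere closed form); adjacency
distance fallback 1.9 Å heavy–heavy and 1.2 Å X–H, used only when
neither explicit connectivity nor a residue template applies.

## Known limitations

* Only the four residue types with sufficient experimental coverage
  are modeled; Cys/Tyr and chain-terminal residues are out of scope.
* Dipoles are consumed, never computed: the package deliberately has
  no force-field layer, and prediction quality on real data inherits
  whatever minimization produced the dipole table.
* The graph has no inter-residue edges and no edge features; distance-
  weighted or multi-relational variants are out of scope.
* Training is CPU-bound pure R; it is sized for datasets of order 10³
  residue graphs (the scale of curated experimental pKa corpora), not
  for proteome-scale screening.
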