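---
title: "Generative modelling of protein contact graphs with cgvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative modelling of protein contact graphs with cgvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgvae)
```

## The problem

A protein is not one structure but an ensemble of them. `cgvae` models
that ensemble at the level of **contact graphs**: a conformation of an
N-residue chain is reduced to its alpha-carbon (CA) trace, and two
residues are connected when their CA–CA distance is no higher than 8 Å —
the threshold conventional in contact-map work. The comparison is
inclusive at the boundary, and no minimum sequence separation is applied
at extraction (trivial |i−j| ≤ 2 contacts are kept; the CASP-RR writer can
filter them on output, since downstream reconstruction tools differ in
their conventions). A conformation is thus a pair (E, F): a binary
symmetric N×N adjacency E, and an N×20 one-hot node-attribute matrix F
recording residue identities. For one protein, F is fixed and the ensemble
lives entirely in E.

Given a per-protein ensemble of conformations (in practice, fragment-
assembly decoy sets), the package fits a **graph variational autoencoder**
to the contact graphs and then samples new graphs from the learned model.
With a KL weight β > 1 the same fit yields a disentangled variant whose
individual latent coordinates can be interpreted by traversal.

## Model

### Encoder

Graph convolutions use the symmetrically normalized adjacency
E′ = D^{−1/2} E D^{−1/2}, with D the diagonal degree matrix of the
self-looped adjacency (self-loops guarantee positive degrees; the encoder
adds them internally, so results do not depend on the stored flag). One
layer is H = act(E′ H_in W). The encoder stacks two such layers (ReLU,
widths 32/32 by default) and then two linear readout paths — one for the
posterior mean, one for the log standard deviation — each a further graph
convolution whose per-node outputs are **mean-pooled** into a single
graph-level vector of length H (default 10).

Two design points deserve comment:

* *Latent granularity.* A per-node latent (one z per residue, as in
  variational graph autoencoders for link prediction) and a graph-level
  latent (one z per conformation) are both defensible. The decoder here
  conditions every node on the same latent vector, and traversal
  interprets single scalar factors, so the graph-level reading is the
  coherent one; mean-pooling the per-node readouts implements it while
  keeping the encoder permutation-equivariant (the pooled posterior is
  invariant under residue relabeling).
* *Posterior scale at initialization.* The log-σ readout carries a
  trainable bias initialized at −1 (σ ≈ 0.37). With σ ≈ 1 at
  initialization, the reparameterization noise is larger than the spread
  of pooled means across conformations, the decoder learns to ignore the
  latent code, and the fit can collapse to reproducing the ensemble mean.
  Starting from a narrow posterior lets the reconstruction signal reach
  the encoder first; the KL term then widens σ as far as the data allow.

### Decoder

The node attributes are not generated — F is copied from the input, so the
decoder only produces edge probabilities. The latent code z passes through
a fully connected ReLU layer to z′; z′ is concatenated with every node's
attribute row to form [z′ ‖ f_i]; a **node-deconvolution** layer maps each
such row through shared weights *plus a trainable per-node bias* to a node
embedding h_i; and a two-stage **edge-deconvolution** scorer produces
symmetric logits from node pairs:

  s_ij = w · ReLU(W (h_i + h_j) + b) + b₀,  P_ij = logistic(s_ij).

Symmetry is by construction (the pair operator depends on the unordered
pair; the symmetrized concatenation [h_i‖h_j] + [h_j‖h_i] reduces
algebraically to the duplicated pair sum, which is why the sum form is
used). Probabilities are clamped to (10⁻¹², 1 − 10⁻¹²).

The per-node bias matters: residues of the same amino-acid type have
identical one-hot rows, so a decoder built solely on [z′ ‖ f_i] is
position-blind within a residue type and cannot represent most contact
graphs. Deconvolution (transposed convolution) layers are positional by
construction — each output slot has its own filters — and the per-node
bias is that positional component in collapsed form.

### Objective

Training minimizes the negative evidence lower bound with a β-weighted KL
term: the reconstruction term is the binary cross-entropy between P and E
over off-diagonal cells (the diagonal is a representation device, and F
contributes only a constant since it is copied), and the KL term is the
closed-form Gaussian divergence −½ Σ_i (1 + log σ_i² − μ_i² − σ_i²) from
the N(0, I) prior. β = 1 is the plain model; β > 1 buys disentanglement at
reconstruction cost; β = 0 removes the prior entirely.

`elbo_loss()` reports the reconstruction as a per-cell *mean* and the KL
as a raw sum, with `total = recon + beta * kl`. For *optimization* those
two conventions must not be mixed at face value: the mean divides the
log-likelihood by the ~N² reconstructed cells, so adding the raw KL
overweights the prior by that factor and collapses the posterior. The
trainer therefore rescales the KL by the cell count
(`kl_norm = "cells"`), making the optimized objective exactly the negative
ELBO divided by a constant. `"nodes"` (divide by N, a convention seen in
graph VAEs) and `"none"` (the face-value mixture) are available for
comparison; both were measurably worse here, `"none"` catastrophically so.
An optional linear KL warm-up (`kl_anneal_epochs`) is provided as a
further guard against posterior collapse, off by default.

## Training

`cgvae()` is the front door: it splits the dataset 4:1 (seeded random
assignment; the 4:1 ratio is conventional, the mechanism a package choice),
initializes all weights Glorot-uniform from the master seed, and runs
mini-batch Adam. The defaults — learning rate 5·10⁻⁴, batch 100, 200
epochs — are sized for full-scale ensembles of tens of thousands of
structures. At desk scale those defaults leave the model
undertrained: for the simulated ensembles used throughout the tests and
the acceptance script (200 decoys of a 30-residue chain, 30 epochs) the
package uses learning rate 5·10⁻³ with batch 5, i.e. roughly a thousand
Adam steps, and for single-graph overfitting checks learning rate 10⁻²,
the standard small-problem Adam setting. Every random draw —
initialization, epoch shuffling, reparameterization noise — derives from
one master seed, and the loss history is bit-reproducible given it. A
non-finite loss aborts with the epoch and batch in the message.

## Generation, reconstruction, traversal

`simulate()` (or `sample_graphs()`) draws z ~ N(0, I), decodes, and
binarizes at threshold 0.5 by default. The binarization rule is a free
parameter of the method: thresholding at 0.5 is the maximum-probability
decision rule, and a top-k alternative (keep the k strongest contacts) is
offered because contact-map-to-structure tools often expect a fixed
contact count. Generated graphs are symmetric, binary and zero-diagonal
by construction.

`traverse_latent()` sweeps one latent coordinate over a grid while fixing
the others (default grid 1, 10, 100, 1000, 10000 — the five-point
log-spaced series used for factor inspection; note it reaches far outside
the N(0, 1) prior, which makes factor effects visible but the decoded
graphs correspondingly extreme). `diff_maps()` turns the series into
signed contact differences so "what does this factor control" becomes a
computable question rather than a visual one.

## The synthetic decoy generator

Real per-protein training sets of tens of thousands of fragment-assembly
decoys are impractical to regenerate, so the package ships a desk-scale
emulator:

* `sample_base_fold()` grows a self-avoiding CA trace: virtual bonds of
  3.8 Å (±1% jitter), non-bonded pairs (|i−j| ≥ 2) rejected below 3.5 Å,
  and a centroid-attraction weight of 0.25 chosen so the radius of
  gyration tracks the empirical globular scaling (≈ 2.2·N^0.38 Å — about
  8 Å at N = 30) and contact density lands in the range typical of small
  single-domain proteins (~0.25–0.35 at N = 30).
* `make_decoy_dataset()` perturbs the base fold with a per-residue
  Gaussian random walk along the chain (step sd `noise_sd`, default 1 Å)
  and re-projects to the base's bond lengths, so deformations are
  correlated along the chain as in real decoy ensembles; each decoy is
  converted to a contact graph, and the base fold's graph is attached as
  the native reference.

What this emulates: fixed N, one sequence, compact folds, unimodal
variability around one basin, NAT-C decreasing with noise. What it does
not: secondary-structure regularity, multi-basin ensembles, energy-guided
sampling, or sequence-dependent geometry. Tests passing on these
ensembles therefore validate the machinery and its statistical behaviour,
not biophysical realism on real decoy sets.

## Evaluation metrics

All metrics operate on the simple graph (self-loops always excluded).

* **Graph-intrinsic properties** per graph: density m/(N(N−1)/2), edge
  count, transitivity (3·triangles / connected triples) and the average
  degree coefficient, read as degree assortativity (Pearson correlation
  of end-point degrees over edge stubs) — that is the standard quantity
  matching the verbal definition. Degenerate cases (no triples; zero
  degree variance) yield NA flags, not errors.
* **Distribution distances** between a generated and a reference set of
  property values: both samples are histogrammed on 20 shared equal-width
  bins spanning the pooled range; PCC is the Pearson correlation of the
  bin-mass vectors (one of several possible readings of "correlation
  between distributions"; the histogram-mass convention is used
  throughout), BD = −log Σ √(p_i q_i) with 10⁻¹⁰ mass smoothing so
  disjoint supports stay finite, and EMD uses the 1-D closed form
  Σ|CDF_a − CDF_b|·binwidth.
* **Native-contact metrics** per graph against a reference structure's
  graph: NAT-C (percentage of native contacts recovered), NONNAT-C
  (non-native contacts per residue), precision, recall, F1, coverage.
  NAT-C/100 coincides with recall by construction; both are reported
  because both names are in common use. "Coverage" is defined in the
  literature as a TP count but reported on a 0–1 scale; the package
  returns the normalized form TP/|native| as `coverage` and the raw count
  as `coverage_raw`, since the exact normalization in the source
  literature is not recoverable.

## Numerical choices

* log σ clamped to [−15, 15] before exponentiation (gradient masked on
  the boundary); BCE probabilities clamped to (10⁻¹², 1 − 10⁻¹²);
  softplus-based cross-entropy on logits inside training for stability.
* Glorot-uniform initialization everywhere, biases zero except the log-σ
  readout bias (−1, see above).
* PDB alternate locations resolved by highest occupancy, ties by altloc
  "A"; anything else is an error rather than a guess.
* Residue indices are 0-free: everything user-visible is 1-based; file
  formats (PDB, CASP-RR) are 1-based as required.

## Problem sizes

The test suite and the acceptance script work at deliberately small
scale, chosen as the smallest sizes at which every statistical property
under test is stable: ensembles of 200 decoys of a 30-residue chain for
the generative experiment (H = 10, 30 epochs, 200 generated graphs, with
an Erdős–Rényi control matched to the training mean density), a
20-residue single graph for overfitting checks, and graphs of N ≤ 15 for
the 100-instance oracle-equivalence sweeps.

## Known limitations

* Models are strictly per-protein: fixed N, fixed sequence; no transfer
  across proteins and no variable-length generation.
* Only residue identity is used as a node attribute; profile or
  solvent-accessibility features are not implemented.
* The decoder scores pairs independently given the latent code, so
  generated graphs need not satisfy hard geometric feasibility (a
  contact-map-to-3D tool is the arbiter of embeddability; the package
  only writes CASP-RR files for one).
* Latent traversal is qualitative; no quantitative disentanglement score
  is computed.
* At desk scale the spread of prior-sampled ensembles occasionally
  undershoots the training spread, most visibly on training ensembles
  whose edge-count distribution is unusually narrow; on such seeds a
  density-matched random-graph control can match the training edge-count
  histogram more closely than the model does.
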