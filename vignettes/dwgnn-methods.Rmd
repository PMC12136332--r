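---
title: "Dynamically weighted GCN-LSTM classification of dynamic functional connectivity: methods and design notes"
author: "dwgnn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dwgnn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dwgnn)
```

## The problem

Early mild cognitive impairment (eMCI) produces subtle disruptions of
resting-state functional connectivity (FC) — the temporal correlation
structure between regional BOLD signals — before overt anatomical change.
`dwgnn` implements an end-to-end classifier of eMCI versus normal controls
(NC) that treats the time-varying FC matrix itself as the *weighted
adjacency* of a graph neural network, rather than flattening FC values
into node features. Node features are instead the weighted-graph local
clustering coefficients of each region, so the model sees both edge
weights (through message passing) and a topological summary per node.

The pipeline is:

1. **Sliding windows.** Each subject's region-by-time matrix
   $\mathbf{X} \in \mathbb{R}^{R \times M}$ is cut into
   $K = \lfloor (M - L)/s \rfloor + 1$ overlapping segments of length $L$
   with step $s$. With the default $L = 30$, $s = 2$ and $M = 137$
   retained volumes (140 acquired, the first 3 discarded for
   magnetization equilibrium) this yields $K = 54$ window graphs.
2. **Low-order dynamic FC.** Per window, the Pearson correlation of every
   region pair (within-window means subtracted).
3. **High-order dynamic FC** (optional). Per window, the similarity
   between two regions' whole connectivity profiles — columns of the
   low-order matrix. As printed in the source model this is an
   *uncentered* cosine similarity; see "Readings of ambiguous formulas".
4. **Edge selection.** Each edge is tested across training subjects with a
   two-sided two-sample t-test on the per-subject window-mean FC; edges
   with $p <$ 0.05 survive, the rest are zeroed in every window. The mask
   is fitted strictly on the training split and frozen.
5. **Node features.** Per window, the weighted local clustering
   coefficient (triangle-intensity form) of each region on the masked
   absolute FC, weights max-normalized per window.
6. **Graph convolution per window.** $H^{(l+1)} = \sigma(\tilde D^{-1/2}
   \tilde A \tilde D^{-1/2} H^{(l)} W^{(l)})$ with $\tilde A = A + I$,
   $\sigma =$ ReLU, widths $1 \to 16 \to 1$, weights shared across the $K$
   windows. Input and output are one scalar per region, so each window
   emits an $R$-vector.
7. **Temporal aggregation.** The $K$ window outputs feed a 3-layer LSTM
   (standard cell: forget/input/output gates and tanh candidate on
   $[h_{k-1}, x_k]$); the final hidden state feeds a fully connected
   softmax head with two outputs.
8. **Training.** Adam at learning rate 0.001, batch size 64, up to 400
   epochs, cross-entropy with L2 penalty and dropout, early stopping on a
   dedicated validation split.
9. **Evaluation.** Confusion counts on held-out test subjects with eMCI
   as positive class, reported as TPR/TNR/PPV/NPV/ACC/F1 percentages, and
   an optional resting-state-network ablation.

## Readings of ambiguous formulas

Three formulas in the source model are ambiguous or garbled as printed;
the package fixes one reading and exposes switches where an alternative
is defensible.

* **Window count.** The printed form "⌊M−L⌋/s+1" is read as
  $\lfloor (M-L)/s \rfloor + 1$: only this reading reproduces the model's
  own count of 54 subnetworks at $M=137$, $L=30$, $s=2$.
* **Clustering coefficient.** The printed formula sums over single
  neighbours, which cannot form a clustering coefficient and is unbounded.
  The package implements the triangle-intensity weighted clustering
  coefficient its cited definition denotes,
  $n_i = \frac{2}{|\mathcal N_i|(|\mathcal N_i|-1)}
  \sum_{j<h \in \mathcal N_i,\ A_{jh}\neq 0}
  (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$,
  which reduces to the binary clustering coefficient for uniform weights
  and is bounded in $[0,1]$ after per-window max-normalization. The
  literal printed form is available behind `eq3Literal = TRUE` for
  comparison only.
* **High-order FC.** The printed definition is an uncentered cosine of
  low-order columns (diagonal included), unlike the mean-centered
  low-order correlation. It is implemented exactly as printed;
  `buildHighOrder(..., centered = TRUE)` provides Pearson-style centering
  for sensitivity analysis.
* **LSTM gate input.** The printed gate argument "$[h_{k-1}, h_k]$"
  conflates hidden and input symbols; the standard reading
  $[h_{k-1}, x_k]$ is used, and the cell-output "tanh$(C_t)$" is read as
  tanh$(C_k)$.

## Design choices where the source is silent

* **Per-subject edge statistic.** The t-test consumes one scalar per
  subject per edge — the FC averaged over the K windows — because
  window-level samples of one subject are strongly autocorrelated and
  would inflate the test's effective sample size.
  `perWindowStack = TRUE` exposes the alternative.
* **Pooled-variance Student test** by default (`welch = TRUE` optional);
  no multiple-testing correction, matching the single stated threshold
  of 0.05.
* **Mask leakage.** Nothing in the source states which subjects the
  t-test saw. Fitting on anything but the training split leaks test
  labels, so the package fits the mask inside the training fold only and
  an explicit test asserts the mask is unchanged by the existence of test
  subjects.
* **Negative FC weights.** Fractional powers and $\tilde D^{-1/2}$ are
  undefined for negative weights; the absolute value is taken before both
  the clustering coefficient and the adjacency normalization
  (`negativePolicy = "abs"`), preserving connection strength;
  `"clip_zero"` discards negative edges instead.
* **Widths.** GCN hidden width 16 and LSTM hidden size 64 per layer
  (3 layers) are package defaults, exposed in `trainConfig()`; the layer
  *counts* (2 GCN, 3 LSTM) follow the stated protocol.
* **Split.** Stratified 70/15/15 train/validation/test by subject.
* **Regularization defaults.** L2 weight 5e-4, dropout 0.5 on LSTM layer
  outputs, early-stopping patience 30 epochs.
* **Shared GCN weights.** One GCN is applied to all K windows; per-window
  weights would multiply parameters by K with no evidence the source did
  so.
* **Classifier head.** A single fully connected layer from the final LSTM
  hidden state to 2 softmax outputs.

## Numerical and implementation notes

* **Initialization.** Weights are Glorot-uniform; GCN weights take the
  *absolute value* of the draw. The GCN path is nonnegative end to end
  (clustering-coefficient features, normalized adjacency with self-loops),
  so with zero-mean weights the width-1 ReLU output unit starts dead —
  all pre-activations nonpositive, zero gradient forever — for a large
  fraction of seeds. Nonnegative initial weights guarantee a live signal
  path without changing the model class. LSTM forget-gate biases start at
  1 so early training does not flush the cell state.
* **Precision and determinism.** All arithmetic is double precision.
  Splits, initialization, batch order and dropout masks derive from the
  single configuration seed; two runs of `runPipeline()` with the same
  configuration are bit-identical (single-threaded BLAS).
* **Gradients.** The LSTM/head forward and backward passes are compiled
  (RcppArmadillo); the per-window GCN runs as sparse block-diagonal
  products over the whole batch. Hand-written backpropagation is verified
  against central finite differences to better than 1e-4 relative error
  on small instances (`gradientCheck()`).
* **Degenerate inputs.** Zero-variance window segments and zero-norm
  connectivity profiles yield correlation/similarity 0 with a warning
  (diagonal stays 1); regions with fewer than two retained neighbours get
  clustering coefficient 0; zero-denominator classification metrics are
  reported as `NA`, never an error; subjects shorter than the window are
  rejected with the subject named.
* **Ablation mechanics.** "Removing a network" zeroes every edge incident
  to its regions in the masked FC and *recomputes* node features and the
  normalized adjacency on the ablated graphs, then re-evaluates the
  trained model without retraining. Zeroing only node features would let
  ablated regions keep influencing message passing through their edges.

## The synthetic cohort generator

Real clinical resting-state cohorts (ADNI and similar repositories) are
access-restricted, so the package ships a generator
(`simSpec()`, `makeCohort()`) whose cohorts exercise every pipeline stage:

* Each subject follows a latent Markov chain over `nStates = 3`
  correlation states (per-step switch probability 0.05), emulating the
  state-switching structure that sliding-window FC is designed to detect.
* State correlation matrices come from a random sparse weighted graph
  (edge density 0.15, weights U(0.2, 0.8)), symmetrized and diagonally
  loaded to positive definiteness — this produces non-trivial triangle
  structure, which the clustering-coefficient features need.
* The eMCI group differs from NC only on the designated effect edges,
  whose state correlations are *reduced* by `effectSize`
  (hypoconnectivity, the typical direction of early-MCI findings); the
  shifted matrices are projected back to the nearest positive-definite
  correlation matrix by deterministic eigenvalue clipping.
* Observations get independent Gaussian noise (`noiseSd = 0.2`).
* Defaults mirror the target acquisition: 116 regions, 137 retained time
  points.

What the generator does **not** emulate: haemodynamic response shape and
temporal autocorrelation of BOLD, scanner drift and motion artefacts,
site effects, and realistic inter-subject variability of the connectome.
Passing the synthetic benchmarks therefore demonstrates that the
implementation recovers planted connectivity differences under its own
model assumptions — not that the published clinical accuracies are
reproducible, which would require the restricted data.

## Problem sizes used by the test suite

The heavier checks run at reduced scale, chosen as the smallest problems
that still exercise the statistics: calibration pools 10,000+ null edge
p-values from cohorts with R = 30 regions and 20 subjects per group;
the signal-recovery benchmark uses R = 30, 60 subjects per group and a
0.5 correlation effect on the 20 edges inside a designated 7-region
network, over five cohorts (seeds 1–5); determinism is checked on a
12-region cohort. Unit oracles run on hundreds of random 3–8 node
instances.

## Known limitations

* The GCN is narrow by construction (scalar in, scalar out per window);
  it modulates and mixes clustering-coefficient features along the FC
  graph rather than learning rich node embeddings. That is the modelled
  architecture, not a restriction of the code.
* With cohorts of a few hundred subjects the validation split is small,
  so early stopping is noisy; the returned checkpoint is the best
  validation loss seen.
* Ablation deltas saturate on single cohorts: the trained model uses the
  whole graph, so removing *any* heavily used network can floor accuracy
  at chance. The planted network separates from the others in the ablation
  contrast only on average over several cohorts.
* High-order FC inherits the uncentered-cosine reading; its values
  concentrate near 1 when low-order matrices are dense, which is why
  edge selection precedes it in importance for that branch.
* `share_gcn_weights = FALSE` (per-window GCN parameters) is deliberately
  not implemented; it would multiply parameters by K and is not supported
  by the stated protocol.
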