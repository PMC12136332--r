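# dwgnn

Classification of early mild cognitive impairment (eMCI) versus normal
controls (NC) from ROI-level resting-state BOLD time series, using a
**dynamically weighted graph neural network**: the time-varying functional
connectivity (FC) matrix acts as the *weighted adjacency* of a per-window
graph convolution, weighted-graph local clustering coefficients act as
node features, and an LSTM aggregates the window sequence into a subject
level prediction.

## Who this is for

Researchers working with parcellated resting-state fMRI (e.g. AAL's 116
regions) who want a reproducible, leakage-safe implementation of the
dynamic-FC + GNN + LSTM classification pipeline — including a synthetic
cohort generator with planted connectivity differences, so every stage is
testable without access-restricted imaging data.

## The model

For a subject with series $\mathbf X \in \mathbb R^{R\times M}$:

1. **Sliding windows**: $K=\lfloor (M-L)/s\rfloor+1$ segments (defaults
   $L=30$, $s=2$; with $M=137$ retained volumes, $K=54$).
2. **Low-order FC**: per-window Pearson correlation
   $\mathrm{lFC}_{ij}(k)$; **high-order FC** (optional): cosine
   similarity between columns of the low-order matrix.
3. **Edge selection**: per-edge two-sided two-sample t-test across
   *training* subjects on the window-mean FC; keep $p<0.05$.
4. **Node features**: weighted local clustering coefficient
   $n_i(k) = \frac{2}{|\mathcal N_i|(|\mathcal N_i|-1)}
   \sum_{j<h\in\mathcal N_i, A_{jh}\neq 0}
   (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$ on the masked $|FC(k)|$.
5. **Graph convolution** per window:
   $H^{(l+1)}(k)=\mathrm{ReLU}\!\big(\tilde D^{-1/2}\tilde A\tilde
   D^{-1/2} H^{(l)}(k) W^{(l)}\big)$, $\tilde A = A + I$, widths
   $1\to16\to1$, weights shared across windows.
6. **LSTM** (3 layers, hidden 64) over the $K$ window outputs; a fully
   connected softmax head classifies NC vs eMCI.
7. **Metrics**: TPR, TNR, PPV, NPV, ACC, F1 (eMCI positive) on held-out
   test subjects, plus a resting-state-network ablation table.

Training: Adam (lr 0.001), batch 64, up to 400 epochs, cross-entropy +
L2 + dropout, early stopping on a dedicated validation split; every run
is a pure function of its configuration seed.

## Worked example

```r
library(dwgnn)

## synthetic cohort: 30 regions, 60 subjects per group, correlation on
## the 20 edges inside regions 1-7 reduced by 0.5 in the eMCI group
sp  <- simSpec(nRegions = 30, nTimepoints = 137, nPerGroup = 60,
               effectEdges = t(combn(7, 2))[1:20, ],
               effectSize = 0.5, seed = 1)
cfg <- runConfig(simSpec = sp, seed = 1, verbose = TRUE,
                 partition = c(rep("DMN", 7), rep("EAN", 5), rep("VN", 5),
                               rep("SMN", 5), rep("SR", 4), rep("CER", 4)))
res <- runPipeline(cfg)
res$report
```

```
[dwgnn] simulate: 120 subjects, R=30
[dwgnn] dynfc: low-order, K=54 windows
[dwgnn] edge_select: 48/435 edges kept (train-only fit)
[dwgnn] graph_features: features 54x30 per subject
[dwgnn] train: stopped after 155 epochs (best 125)
[dwgnn] evaluate: test ACC 94.44% on 18 subjects
[dwgnn] ablate: 6 networks ablated
MetricReport (positive class: eMCI)
  counts: TP=9 TN=8 FP=1 FN=0
  TPR=100.00% TNR=88.89% PPV=90.00% NPV=100.00% ACC=94.44% F1=94.74%
```

The 54 sliding-window FC graphs, sparsified by train-only t-tests (48 of
435 edges survive), are classified at 94.4% held-out accuracy.
`res$ablation` tabulates the accuracy drop after removing each
resting-state network from the *trained* model's inputs; averaged over
several cohorts the planted "DMN" block degrades accuracy the most
(single runs can saturate — removing any heavily used network may floor
the classifier). A thin command-line driver with `simulate` / `fc` /
`select` / `train` / `evaluate` / `ablate` / `run-all` subcommands lives
at `inst/cli/dwgnn.R`.

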