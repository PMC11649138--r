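---
title: "Dual-fusion stacked graph convolution for multi-omics prognosis"
author: "omicsSGCN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-fusion stacked graph convolution for multi-omics prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

omicsSGCN predicts a binary survival-risk label for cancer patients from
several omics layers — typically mRNA expression, DNA methylation, miRNA
expression and copy-number variation — measured on a common cohort. Two
complementary fusion channels feed a stacked graph convolutional network
(SGCN):

* **Feature channel.** Each preprocessed, feature-selected layer
  $Z^{(k)} \in \mathbb{R}^{n \times d_k}$ receives a learned per-feature
  attention vector $\alpha^{(k)} = \mathrm{softmax}\!\big(W_2^{(k)}
  \tanh(W_1^{(k)} h^{(k)} + b^{(k)})\big) \in \mathbb{R}^{d_k}$, where
  $h^{(k)}$ is the column mean of $Z^{(k)}$ and the scoring network has a
  hidden width $d$ (default 140). Weighted layers are projected by learned
  maps $P^{(k)} \in \mathbb{R}^{d_k \times d_f}$ and summed into
  $Z^{\mathrm{fusion}} \in \mathbb{R}^{n \times d_f}$ (default
  $d_f = 128$); a concatenation mode is available as an alternative.
* **Sample channel.** Per-layer patient-similarity graphs are built by
  connecting each sample to its $k$ nearest neighbours (default $k = 12$)
  with exponential-kernel weights
  $\exp\!\big(-\rho^2(x_i, x_j)/(\mu\,\delta^2)\big)$, where $\rho$ is the
  Euclidean distance, $\mu = 0.5$, and $\delta^2$ is the median squared
  distance over distinct sample pairs. The directed relation is
  symmetrised as $(W + W^\top)/2$, the per-layer graphs are averaged, and
  the fused adjacency is normalised to the convolution operator
  $\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$, whose spectrum lies in
  $[-1, 1]$.

The SGCN applies $L$ blocks (default 5)
$$Z^{(l+1)} = \sigma\!\big(\tanh(\hat A\, Z^{(l)} W_1^{(l)})\, W_2^{(l)}\big),
\qquad Z^{(0)} = Z^{\mathrm{fusion}},$$
with $\hat A$ entering exactly once per block, so each additional block
extends every sample's receptive field by one hop. A classifier head (one
relu hidden layer, then a linear softmax layer) emits the high-risk
probability $p_i$; training minimises the binary cross-entropy
$-\tfrac1n \sum_i [y_i \log p_i + (1 - y_i)\log(1 - p_i)]$ plus an L2
penalty on weight matrices. All parameters — attention scorers,
projections, convolution blocks and head — are trained jointly by
backpropagation with Adam.

# The pipeline around the model

**Preprocessing** is a fixed four-step sequence: (1) sample intersection
across all layers and the clinical table, ordered by sorted ID; (2)
missingness filtering (features with *strictly more than* 20% missing are
dropped; optionally exact zeros are first recoded as missing, the default
intent for expression-like layers where zero means unmeasured) followed by
per-feature median imputation; (3) variance thresholding (population
variance strictly above a per-layer threshold; conventional starting
points are 7 for mRNA, 0.02 for methylation, 0.1 for CNV and 0 — no filter
— for miRNA, whose threshold is not standardised); (4) z-scoring each
feature to mean 0 and population variance 1. Variances use the population
convention (divide by $n$) throughout; one convention had to be fixed and
this one makes "variance after z-scoring" exactly 1.

**Feature selection** is the hybrid of two views: the features with
nonzero coefficients in an L1-penalised least-squares fit of the 0/1 label
(the label treated as a continuous response, matching the penalised
least-squares formulation; $\lambda$ chosen by 5-fold cross-validation by
default), unioned with the top-$K$ features by random-forest out-of-bag
permutation importance (default $K = 100$, 500 trees). The forest ranking
supplements features the L1 penalty discards, so the union's recall of
informative features is never below the LASSO's alone. Nonzero means
$|\omega| > 10^{-8}$; forest ties break by feature ID so rankings are
reproducible under a fixed seed.

**Risk labels.** Public survival tables rarely ship a ready-made binary
risk label, so the package derives one explicitly: high risk if death is
observed at or before a horizon (default 3 years = 1095 days), low risk if
the sample survives past the horizon regardless of censoring status, and
*excluded* if censored at or before the horizon (such samples carry no
information about horizon survival). The horizon is a modelling choice and
is deliberately a visible, tunable argument.

**Evaluation protocol.** Repeated stratified hold-out: 70% training / 30%
test, repeated (default 10 times), metrics aggregated as mean ± sd.
Feature selection is refit inside each training split by default
(leakage-safe); a whole-cohort mode exists for comparison but leaks label
information into the feature set. Metrics are accuracy, precision, recall,
F1 at the 0.5 threshold, and the rank-based (Mann–Whitney) AUC, which is
invariant under monotone transforms of the scores and reported as
undefined for single-class test sets.

**Graph semantics during training.** The default is transductive: the
fused graph is built over training *and* test samples from features only —
labels never enter graph construction — and mini-batches of the training
mask (batch size 32) contribute to the loss while the forward pass always
runs on the full graph. This follows standard semi-supervised node
classification; sub-graph sampling would change the operator $\hat A$ and
with it the method. An inductive mode restricts neighbour candidates and
the kernel scale to training samples, so held-out samples attach to
training neighbours only and never link to each other.

**Survival analysis.** Predicted probabilities are split at their median
(strictly above the median is high risk; ties go low), Kaplan–Meier
curves are estimated per group and compared with the two-group log-rank
test (chi-square, 1 df). Deaths are processed before censorings at tied
times, the standard convention. The "risk score" here is the predicted
probability — the classifier emits no hazard ratio.

# Ablation variants

Six named variants toggle the architecture for controlled comparisons:
`dualFusion` (full model), `sgcnSingleOmics` (one layer, its own graph, no
attention), `noAttentionSGCN` (concatenated layers + fused graph + SGCN),
`noAttentionFF` (concatenated layers + feedforward head only),
`attentionFF` (attention fusion + feedforward head only) and
`withoutGraph` (full model with $\hat A$ replaced by the identity). With
the identity operator each convolution block is exactly a two-map
feedforward block, which is what the feedforward ablations use — the test
suite verifies this equivalence against an independently coded oracle.

# Design decisions in the open

Several pieces of the architecture are underdetermined by the usual
write-ups of this model family; the package fixes them as follows.

* **Attention shape.** The published scoring form is dimensionally
  inconsistent if read literally (a $d_k \times d$ map applied to a
  $d_k$-vector yielding a $d_k$-vector). The minimal structure honouring
  both the stated shapes and the stated output is a two-map scorer through
  the $d$-unit hidden layer, as implemented. The layer summary $h^{(k)}$
  is the column mean over samples — the simplest sample-independent
  summary consistent with "one weight per feature".
* **Fusing layers of unequal width.** A plain weighted sum of layers is
  undefined when the $d_k$ differ; the package inserts learnable
  projections $P^{(k)}$ to a common width before summation (default), with
  weighted concatenation as the documented alternative.
* **Attention scale.** The weighted layer is computed as
  $d_k\,\alpha^{(k)} \odot Z^{(k)}$ (mean column weight 1), not
  $\alpha^{(k)} \odot Z^{(k)}$ (mean weight $1/d_k$). With z-scored
  features and $d_k$ in the hundreds, the $1/d_k$ scale shrinks the fused
  representation to a standard deviation of order $10^{-2}$; the tanh and
  sigmoid nonlinearities then operate in their flat/linear region and
  training cannot leave chance — observed directly during development.
  The rescaling is a reparameterisation: the softmax weights still sum
  to 1, are non-negative, and are what the package records and exports;
  uniform attention leaves a layer unchanged.
* **Initialisation.** Plain Xavier initialisation makes the 5-block
  tanh/sigmoid stack untrainable: each sigmoid attenuates the forward
  signal roughly fourfold (slope $1/4$ at 0) and emits low-variance
  values in $(0,1)$, so by block 5 the class signal is numerically gone.
  Block weights are therefore initialised with gain corrections —
  $W_1^{(l)}$ scaled by 2 (low-variance block inputs) and $W_2^{(l)}$ by
  4 (sigmoid slope) — which restores signal propagation and learning at
  depth 5. Shallow stacks and the feedforward ablations train either way.
* **Recursion.** A literal reading of the block equation feeds
  $Z^{\mathrm{fusion}}$ into *every* block, which would make stacking
  vacuous; blocks are recursive ($Z^{(l)}$ is each block's input), which
  is what "progressively expanding the receptive field" requires.
* **Head.** The head is one relu hidden layer (default width 32) followed
  by a linear softmax layer; probabilities are clipped to
  $[10^{-12}, 1 - 10^{-12}]$ inside the loss.
* **Block activation.** The per-block sigmoid is kept exactly as specified
  despite being unusual for hidden layers; a `blockActivation = "relu"`
  switch exists for comparison and defaults off.

# Numerical conventions and degenerate inputs

Distance ties at the $k$-th neighbour keep the lower sample ID; $\delta^2$
excludes self-pairs (their zero distance would bias the median downward);
a dataset in which all samples coincide is rejected as degenerate
geometry. Zero-variance features are an error in z-scoring (and are
removed by any variance filter with threshold $\ge 0$). All-identical
predicted risks make the median split meaningless and raise an error. A
test set with a single class yields an undefined AUC; other metrics are
still computed. Softmax computations subtract the row maximum before
exponentiation. Mini-batch partitions, dropout masks (rate 0.2 on each
block's input, training only) and initialisation all draw from R's seeded
generator, so a seed fixes the entire run bit-for-bit.

# The synthetic generator

Real cohorts for this model family are access-controlled downloads, so the
package ships a generator that emulates the *structure* the method
assumes: $K$ omics blocks of differing width on common samples (defaults
200/150/60/100, $n = 300$); two latent risk classes (proportion 0.5)
shifting a per-block subset of informative features by ±effect/2 (defaults
15 per block, effect 1.5 in noise-sd units); cross-omics shared latent
factors inducing correlated structure (3 factors, loading sd 0.3 — visible
correlation without swamping the class signal); exponential survival with
a class hazard ratio (default 3, baseline median survival 3 years) and
independent exponential censoring solved numerically to hit the target
censoring fraction (default 0.3); and optional missingness (default 5%).
Signal placement modes relocate the informative features: every block,
one block only, or disjoint subsets per block so that no single layer
holds the full signal — the configuration used to test that multi-omics
integration beats any single layer. Because the class shifts the means of
informative features, the kNN graphs built from selected features are
genuinely class-informative, which is what makes the graph-ablation
comparisons meaningful. The generator's Gaussian structure also yields the
Bayes-optimal accuracy in closed form (`bayesAccuracy()`), used as an
analytic ceiling when interpreting pipeline results.

What the generator does *not* emulate: heavy-tailed and zero-inflated
expression marginals, batch effects, block-structured LD-like feature
correlation, informative censoring, and class imbalance beyond the
configured proportion. Passing tests on these data therefore demonstrate
the correctness and internal consistency of the implementation, not
clinical performance on real cohorts.

# Problem sizes used by the test suite

The statistical checks run at sizes chosen for a single-CPU desk machine:
signal recovery uses the generator defaults ($n = 300$, four blocks,
effect 1.5) over 10 seeds with training shortened to 200 epochs, and the
null configuration (effect 0) over 10 seeds at 50 epochs; the
multi-vs-single-omics comparison uses $n = 150$ with blocks of width
60/50/40/50, 3 informative features per block (so no single layer is
sufficient) and 100 epochs over 10 hold-out repeats; the graph-ablation
comparison uses the same cohort shape with 10 informative features per
block — enough that the classes form clusters and the kNN graph carries
class structure, the regime the comparison is about — with selection
refit inside each split; log-rank calibration uses 1000 null
simulations of $n = 100$. The gradient check runs on a 6-sample, 2-block
toy through the full attention + 5-block + head stack against 4th-order
central differences.

# Known limitations

The dense $n \times n$ operator limits cohorts to a few thousand samples;
the per-block sigmoid requires the gain-corrected initialisation described
above and remains the architecture's most fragile element at depth;
transductive training means adding samples requires retraining; and the
derived risk label discards early-censored samples rather than modelling
them. Cox-style continuous-risk modelling and multivariate clinical
adjustment are out of scope.
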