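# omicsSGCN

Binary survival-risk prediction for cancer cohorts from multi-omics data
(mRNA expression, DNA methylation, miRNA expression, copy-number
variation), built around a **dual fusion** strategy feeding a **stacked
graph convolutional network (SGCN)**. The package is aimed at
computational biologists who have several omics matrices and a clinical
survival table on a common cohort and want a prognostic classifier plus
risk-stratified survival analysis.

## The model

Two fusion channels are learned jointly:

* **Feature fusion with attention.** Each selected omics layer
  `Z(k) ∈ R^{n×d_k}` gets per-feature attention weights
  `α(k) = softmax(W2(k) tanh(W1(k) h(k) + b(k)))`, with `h(k)` the column
  mean of the layer and a scoring hidden width `d = 140`. Attention-scaled
  layers are projected to a common width (`d_f = 128`) and summed into
  `Z(fusion)`.
* **Graph fusion.** Per-layer patient kNN graphs (`k = 12`) with
  exponential-kernel weights `exp(−ρ²/(μ δ²))` (`μ = 0.5`, `δ²` = median
  squared pairwise distance) are averaged and normalised into the
  convolution operator `Â = D̃^{−1/2}(A + I)D̃^{−1/2}`.

The SGCN stacks five blocks `Z(l+1) = sigmoid(tanh(Â Z(l) W1(l)) W2(l))`
over the fused graph and features, followed by a relu/softmax head;
everything is trained end-to-end with Adam (lr 0.001, batch 32, dropout
0.2, weight decay 0.001) on a masked cross-entropy over the training
samples, transductively on the full graph.

Around the core: four-step preprocessing (sample intersection,
missingness filter + median imputation, variance threshold, z-score),
hybrid LASSO ∪ top-100 random-forest-importance feature selection,
repeated stratified 70/30 hold-out evaluation (ACC/precision/recall/F1/
AUC), six ablation variants, Kaplan–Meier + log-rank risk stratification,
and a seeded synthetic multi-omics generator with known ground truth.

## Worked example

```r
library(omicsSGCN)

# simulate a 4-block multi-omics cohort with survival outcomes
ds <- generateMultiOmics(syntheticConfig(nSamples = 200, seed = 42))

# 4-step preprocessing: intersect, filter+impute, variance filter, z-score
mats <- preprocessPipeline(ds$matrices, ds$clinical, preprocessConfig())

# binary risk labels at the 3-year horizon (censored-early samples excluded)
labels <- deriveRiskLabels(ds$clinical, horizonDays = 1095)$labels
mats <- lapply(mats, function(m)
  OmicsMatrix(assayValues(m)[names(labels), , drop = FALSE], omicsName(m)))

# hybrid LASSO / random-forest selection on one layer
rlassoSelect(mats$mRNA, labels, lassoConfig("cv"),
             forestConfig(nTrees = 300, topK = 50, seed = 1))
#> SelectionResult 'mRNA': 17 LASSO + 50 forest top-K -> 57 selected
```

Training the full model on a stratified 70% split (selection refit on the
training samples per layer) and evaluating the held-out 30%:

```r
model <- trainSgcn(selMats, labels, tr, variantSpec("dualFusion"),
                   trainConfig(epochs = 150), seed = 1)
evaluateModel(model, selMats, labels, te)
#> EvaluationReport over 1 repeat(s):
#>   accuracy  0.8182 +/- 0.0000
#>   precision 0.9375 +/- 0.0000
#>   recall    0.8333 +/- 0.0000
#>   f1        0.8824 +/- 0.0000
#>   auc       0.7812 +/- 0.0000
```

So 82% of held-out samples are classified into the correct risk group,
and a random high-risk sample receives a higher predicted risk than a
random low-risk one 78% of the time. Stratifying all predictions at the
median risk and comparing observed survival:

```r
surv <- survivalAnalysis(predictRisk(model, selMats), clinical)
print(surv$logrank)
#> Log-rank test: chi-square = 25.7530 (1 df), p = 3.88e-07
#>   group sizes 74/75, observed events 73/68, expected 46.11/94.89
```

The predicted high-risk group dies far faster than expected under the
null of equal hazards — the stratification is strongly prognostic on this
synthetic cohort. `repeatedHoldout()` wraps the split/train/evaluate loop
(10 repeats, mean ± sd), `crossValidate()` is the stratified k-fold
alternative, `sweepParameter()` scans `kNeighbors`, attention
width or depth, and `variantSpec()` selects the ablations
(`noAttentionSGCN`, `attentionFF`, `withoutGraph`, ...). A thin CLI over
the same functions lives in `inst/cli/omics-sgcn.R`
(`simulate`/`preprocess`/`select`/`train`/`survival`).

## Scope notes

The synthetic generator emulates the statistical structure this model
family assumes (class-informative feature subsets, shared cross-omics
factors, class-dependent hazards with censoring); it does not reproduce
any real cohort's marginals, and results on it validate the
implementation, not clinical performance. See the methods vignette
(`vignettes/dual-fusion-sgcn.Rmd`) for the model, design decisions and
limitations.
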