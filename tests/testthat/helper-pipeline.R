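# End-to-end pipeline helper used by the acceptance-style tests: generate,
# preprocess, stratified split, selection refit on the training split,
# train one variant, evaluate on the held-out samples.

runPipelineSeed <- function(seed, cfg = syntheticConfig(seed = seed),
                            variant = variantSpec("dualFusion"),
                            epochs = 200, selection = "rlasso",
                            trees = 500) {
  ds <- generateMultiOmics(cfg)
  mats <- preprocessPipeline(ds$matrices, ds$clinical, preprocessConfig())
  y <- ds$labels
  yv <- as.integer(y[sampleIds(mats[[1]])])
  set.seed(seed)
  tr <- asNamespace("omicsSGCN")$stratifiedSplit(yv, 0.7)
  te <- setdiff(seq_along(yv), tr)
  if (selection == "rlasso") {
    mats <- lapply(mats, function(m) {
      mtr <- OmicsMatrix(assayValues(m)[tr, , drop = FALSE], omicsName(m))
      s <- suppressWarnings(rlassoSelect(mtr, y, lassoConfig(),
                                         forestConfig(nTrees = trees,
                                                      seed = seed)))
      OmicsMatrix(assayValues(m)[, selectedFeatures(s), drop = FALSE],
                  omicsName(m))
    })
  }
  model <- trainSgcn(mats, y, tr, variant, trainConfig(epochs = epochs),
                     seed = seed)
  list(report = reportPerRepeat(evaluateModel(model, mats, y, te)),
       model = model, dataset = ds, matrices = mats, train = tr, test = te)
}
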