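# Training/evaluation tests run on a deliberately small generated dataset
# (60 samples, 2 omics blocks, strong signal) so the whole file stays fast.

test_that("evaluation metrics match the closed-form oracle exactly", {
  ns <- asNamespace("omicsSGCN")
  # the worked confusion example
  mt <- ns$metricsFromCounts(3, 4, 1, 2)
  expect_equal(unname(mt), c(0.70, 0.75, 0.60, 2 * 0.75 * 0.6 / 1.35))

  set.seed(55)
  for (rep in 1:100) {
    cts <- rmultinom(1, sample(10:200, 1), prob = runif(4, 0.05, 1))[, 1]
    TP <- cts[1]; TN <- cts[2]; FP <- cts[3]; FN <- cts[4]
    mt <- ns$metricsFromCounts(TP, TN, FP, FN)
    expect_identical(mt[["accuracy"]], (TP + TN) / sum(cts))
    prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
    rec <- if (TP + FN == 0) 0 else TP / (TP + FN)
    expect_identical(mt[["precision"]], prec)
    expect_identical(mt[["recall"]], rec)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_identical(mt[["f1"]], f1)
    expect_true(all(mt >= 0 & mt <= 1))
  }
})

test_that("AUC is the rank statistic and is monotone invariant", {
  y <- c(1, 1, 0, 0, 0)
  p <- c(0.9, 0.4, 0.5, 0.2, 0.1)
  # pairs (pos > neg): (0.9 beats all 3) + (0.4 beats 0.2, 0.1) = 5 of 6
  expect_equal(aucRank(p, y), 5 / 6)
  expect_equal(aucRank(qlogis(p), y), 5 / 6)       # monotone transform
  expect_equal(aucRank(rep(0.7, 5), y), 0.5)       # constant scores
  expect_true(is.na(aucRank(p, rep(1, 5))))        # single class
  expect_equal(aucRank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
})

test_that("untrained models predict chance; training learns the signal", {
  ds <- smallDataset(seed = 101)
  mats <- zscoreAll(ds$matrices)
  y <- ds$labels
  tr <- 1:42; te <- 43:60

  m0 <- trainSgcn(mats, y, tr, variantSpec("dualFusion"),
                  trainConfig(epochs = 0), gcfg = graphConfig(kNeighbors = 5),
                  seed = 2)
  r0 <- reportPerRepeat(evaluateModel(m0, mats, y, te))
  expect_lt(abs(r0$accuracy - 0.5), 0.35)  # near chance, small test set

  m1 <- trainSgcn(mats, y, tr, variantSpec("dualFusion"),
                  trainConfig(epochs = 60), gcfg = graphConfig(kNeighbors = 5),
                  acfg = attentionConfig(hiddenUnits = 20, fusionDim = 16),
                  scfg = sgcnConfig(nLayers = 2, hidden = 16),
                  seed = 2)
  r1 <- reportPerRepeat(evaluateModel(m1, mats, y, te))
  expect_gte(r1$accuracy, 0.85)
  # loss mostly decreasing; increases below 0.01 count as minibatch noise
  expect_gte(mean(diff(m1@history) <= 0.01), 0.9)
  expect_lt(m1@history[length(m1@history)], m1@history[1])
})

test_that("training is reproducible under a fixed seed", {
  ds <- smallDataset(seed = 102)
  mats <- zscoreAll(ds$matrices)
  y <- ds$labels
  a <- trainSgcn(mats, y, 1:42, variantSpec("dualFusion"),
                 trainConfig(epochs = 10), gcfg = graphConfig(kNeighbors = 5),
                 scfg = sgcnConfig(nLayers = 2, hidden = 8), seed = 9)
  b <- trainSgcn(mats, y, 1:42, variantSpec("dualFusion"),
                 trainConfig(epochs = 10), gcfg = graphConfig(kNeighbors = 5),
                 scfg = sgcnConfig(nLayers = 2, hidden = 8), seed = 9)
  expect_identical(a@history, b@history)
  expect_identical(a@params, b@params)
})

test_that("training validates its inputs", {
  ds <- smallDataset(seed = 103)
  mats <- zscoreAll(ds$matrices)
  y <- ds$labels
  expect_error(trainSgcn(mats, y, integer(0)), "empty training mask")
  oneClass <- y; oneClass[] <- 1L
  expect_error(trainSgcn(mats, oneClass, 1:20,
                         gcfg = graphConfig(kNeighbors = 5)),
               "single class")
})

test_that("ablation variants toggle the advertised components", {
  expect_true(variantSpec("dualFusion")$useAttention)
  expect_false(variantSpec("noAttentionSGCN")$useAttention)
  expect_false(variantSpec("withoutGraph")$useGraph)
  expect_true(variantSpec("withoutGraph")$useSgcn)
  expect_false(variantSpec("attentionFF")$useSgcn)
  expect_error(variantSpec("bogus"))

  ds <- smallDataset(seed = 104)
  mats <- zscoreAll(ds$matrices)
  y <- ds$labels
  # single-omics variant consumes exactly one layer
  ms <- trainSgcn(mats, y, 1:42, variantSpec("sgcnSingleOmics", omicsIndex = 2),
                  trainConfig(epochs = 5), gcfg = graphConfig(kNeighbors = 5),
                  scfg = sgcnConfig(nLayers = 2, hidden = 8), seed = 4)
  expect_length(ms@featureIds, 1)
  expect_identical(ms@featureIds[[1]], featureIds(mats[[2]]))
  p <- predictRisk(ms, mats)
  expect_equal(nrow(p), 60)
  # identity-graph variant stores no graph
  mw <- trainSgcn(mats, y, 1:42, variantSpec("withoutGraph"),
                  trainConfig(epochs = 5),
                  scfg = sgcnConfig(nLayers = 2, hidden = 8), seed = 4)
  expect_null(mw@config$graphObject)
})

test_that("repeated hold-out aggregates per-repeat metrics", {
  ds <- smallDataset(seed = 105)
  mats <- zscoreAll(ds$matrices)
  y <- ds$labels
  rep1 <- repeatedHoldout(mats, y, variantSpec("noAttentionFF"),
                          nRepeats = 1, seed = 3,
                          tcfg = trainConfig(epochs = 30),
                          gcfg = graphConfig(kNeighbors = 5),
                          scfg = sgcnConfig(nLayers = 2, hidden = 8),
                          selection = "none")
  expect_equal(nrow(reportPerRepeat(rep1)), 1)
  expect_true(all(reportSummary(rep1)$sd == 0))  # single repeat: sd 0

  rep3a <- repeatedHoldout(mats, y, variantSpec("noAttentionFF"),
                           nRepeats = 3, seed = 3,
                           tcfg = trainConfig(epochs = 30),
                           gcfg = graphConfig(kNeighbors = 5),
                           scfg = sgcnConfig(nLayers = 2, hidden = 8),
                           selection = "none")
  rep3b <- repeatedHoldout(mats, y, variantSpec("noAttentionFF"),
                           nRepeats = 3, seed = 3,
                           tcfg = trainConfig(epochs = 30),
                           gcfg = graphConfig(kNeighbors = 5),
                           scfg = sgcnConfig(nLayers = 2, hidden = 8),
                           selection = "none")
  expect_identical(reportPerRepeat(rep3a), reportPerRepeat(rep3b))
  s <- reportSummary(rep3a)
  expect_true(all(s$mean[s$metric != "auc"] >= 0 &
                    s$mean[s$metric != "auc"] <= 1))
  # confusion counts account for every evaluated sample
  pr <- reportPerRepeat(rep3a)
  expect_true(all(pr$TP + pr$TN + pr$FP + pr$FN == 18))  # 30% of 60
})

test_that("parameter sweeps tabulate one aggregate per value", {
  ds <- smallDataset(seed = 106)
  mats <- zscoreAll(ds$matrices)
  y <- ds$labels
  tab <- sweepParameter("nLayers", c(1, 2),
                        matrices = mats, labels = y,
                        variant = variantSpec("noAttentionSGCN"),
                        nRepeats = 1, seed = 5,
                        tcfg = trainConfig(epochs = 10),
                        gcfg = graphConfig(kNeighbors = 5),
                        scfg = sgcnConfig(hidden = 8),
                        selection = "none")
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$accuracy_mean >= 0 & tab$accuracy_mean <= 1))
  expect_error(sweepParameter("nLayers", c(2, 2), matrices = mats,
                              labels = y), "duplicate")
  expect_error(sweepParameter("nLayers", 2, matrices = mats, labels = y),
               "two values")
})

test_that("inductive graphs restrict neighbours to training samples", {
  ds <- smallDataset(seed = 107)
  mats <- zscoreAll(ds$matrices)
  tr <- 1:40
  g <- buildFusedGraph(mats, graphConfig(kNeighbors = 5), trainIdx = tr)
  expect_s4_class(g, "NormalizedGraph")
  ns <- asNamespace("omicsSGCN")
  sg <- ns$buildKnnGraphInductive(mats[[1]], tr, graphConfig(kNeighbors = 5))
  A <- adjacency(sg)
  # test-test block must be all zero: held-out samples never link directly
  expect_true(all(A[41:60, 41:60] == 0))
})
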