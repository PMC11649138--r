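#' Training configuration
#'
#' @param learningRate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 1000).
#' @param batchSize mini-batch size (default 32). Batches partition the
#'   training mask; the forward pass always runs over the full graph and
#'   only the batch's samples contribute to the loss.
#' @param weightDecay L2 penalty on weight matrices (default 0.001).
#' @param transductive if `TRUE` (default) the similarity graph is built
#'   over training and test samples jointly (features only, labels never
#'   enter graph construction); if `FALSE`, neighbour candidates are
#'   restricted to training samples so test features cannot shape edges
#'   among training nodes.
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(learningRate = 0.001, epochs = 1000, batchSize = 32,
                        weightDecay = 0.001, transductive = TRUE) {
  stopifnot(learningRate > 0, epochs >= 0, batchSize >= 1, weightDecay >= 0)
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 weightDecay = weightDecay, transductive = transductive),
            class = "trainConfig")
}

#' Ablation variant specification
#'
#' Named toggles for the model variants: the full dual-fusion model and
#' the ablations that drop the attention layer, the graph, the stacked
#' graph convolution, or restrict to one omics layer.
#'
#' @param name one of `"dualFusion"` (attention fusion + fused graph +
#'   stacked GCN), `"sgcnSingleOmics"` (stacked GCN on a single layer's
#'   graph, no attention), `"noAttentionSGCN"` (concatenated features +
#'   fused graph + stacked GCN), `"noAttentionFF"` (concatenated features +
#'   feedforward head only), `"attentionFF"` (attention fusion +
#'   feedforward head only), `"withoutGraph"` (full model with the
#'   convolution operator replaced by the identity).
#' @param omicsIndex for `"sgcnSingleOmics"`, which layer to use.
#' @return a `variantSpec` list with toggles `useAttention`, `useGraph`,
#'   `useSgcn`, `omicsIndex`.
#' @export
variantSpec <- function(name = c("dualFusion", "sgcnSingleOmics",
                                 "noAttentionSGCN", "noAttentionFF",
                                 "attentionFF", "withoutGraph"),
                        omicsIndex = 1L) {
  name <- match.arg(name)
  v <- switch(name,
    dualFusion      = list(useAttention = TRUE,  useGraph = TRUE,  useSgcn = TRUE),
    sgcnSingleOmics = list(useAttention = FALSE, useGraph = TRUE,  useSgcn = TRUE),
    noAttentionSGCN = list(useAttention = FALSE, useGraph = TRUE,  useSgcn = TRUE),
    noAttentionFF   = list(useAttention = FALSE, useGraph = FALSE, useSgcn = FALSE),
    attentionFF     = list(useAttention = TRUE,  useGraph = FALSE, useSgcn = FALSE),
    withoutGraph    = list(useAttention = TRUE,  useGraph = FALSE, useSgcn = TRUE))
  v$name <- name
  v$omicsIndex <- as.integer(omicsIndex)
  structure(v, class = "variantSpec")
}

#' Build the fused, normalised patient graph from omics layers
#'
#' Builds one kNN similarity graph per layer, averages them, and returns
#' the symmetric normalised convolution operator. With `trainIdx` given
#' (inductive mode), neighbour candidates and the kernel scale are
#' restricted to training samples; held-out samples attach to training
#' neighbours only.
#'
#' @param matrices list of sample-aligned [OmicsMatrix-class] objects.
#' @param gcfg a [graphConfig()].
#' @param trainIdx optional integer indices of training samples.
#' @return a [NormalizedGraph-class].
#' @export
buildFusedGraph <- function(matrices, gcfg = graphConfig(),
                            trainIdx = NULL) {
  graphs <- lapply(matrices, function(m) {
    if (is.null(trainIdx)) buildKnnGraph(m, gcfg)
    else buildKnnGraphInductive(m, trainIdx, gcfg)
  })
  normalizeAdjacency(fuseGraphs(graphs))
}

# kNN graph whose neighbour candidates are training samples only; the
# kernel scale delta^2 comes from train-train pairs.
buildKnnGraphInductive <- function(m, trainIdx, cfg = graphConfig()) {
  x <- assayValues(m)
  n <- nrow(x)
  k <- cfg$kNeighbors
  if (length(trainIdx) <= k)
    stop("need more training samples than kNeighbors")
  d2 <- as.matrix(stats::dist(x))^2
  dtr <- d2[trainIdx, trainIdx]
  delta2 <- stats::median(dtr[upper.tri(dtr)])
  if (delta2 == 0) stop("degenerate geometry: all samples identical")
  kern <- exp(-d2 / (cfg$mu * delta2))
  ids <- rownames(x)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(trainIdx, i)
    ord <- cand[order(d2[i, cand], ids[cand], method = "radix")]
    nb <- ord[seq_len(k)]
    W[i, nb] <- kern[i, nb]
  }
  A <- (W + t(W)) / 2
  diag(A) <- 0
  dimnames(A) <- list(ids, ids)
  new("SampleGraph", sampleIds = ids, adjacency = A)
}

#' Train a dual-fusion stacked-GCN model
#'
#' Minimises the masked cross-entropy plus L2 penalty with Adam. Every
#' epoch partitions the training mask into shuffled mini-batches; the
#' forward pass always uses all samples' features and the full graph, and
#' only the batch's samples contribute to the loss (standard masked
#' transductive training). Dropout is applied to each graph-convolution
#' block's input during training only. Runs are reproducible under a fixed
#' seed.
#'
#' @param matrices list of sample-aligned [OmicsMatrix-class] objects
#'   (typically the selected, z-scored features).
#' @param labels named 0/1 vector; at least the training samples must be
#'   labelled.
#' @param trainMask integer indices (into the common sample order) of the
#'   training samples.
#' @param variant a [variantSpec()].
#' @param tcfg,gcfg,acfg,scfg configuration lists ([trainConfig()],
#'   [graphConfig()], [attentionConfig()], [sgcnConfig()]).
#' @param graph optional precomputed [NormalizedGraph-class] to reuse.
#' @param seed integer seed for initialisation, batching and dropout.
#' @return an [SgcnModel-class].
#' @export
trainSgcn <- function(matrices, labels, trainMask,
                      variant = variantSpec("dualFusion"),
                      tcfg = trainConfig(), gcfg = graphConfig(),
                      acfg = attentionConfig(), scfg = sgcnConfig(),
                      graph = NULL, seed = 1L) {
  if (variant$name == "sgcnSingleOmics")
    matrices <- matrices[variant$omicsIndex]
  ids <- sampleIds(matrices[[1L]])
  for (m in matrices)
    if (!identical(sampleIds(m), ids)) stop("sample misalignment across omics")
  if (length(trainMask) == 0L) stop("empty training mask")
  y <- rep(NA_integer_, length(ids))
  names(y) <- ids
  common <- intersect(ids, names(labels))
  y[common] <- as.integer(labels[common])
  ytr <- y[trainMask]
  if (anyNA(ytr)) stop("unlabelled sample(s) in training mask")
  if (length(unique(ytr)) < 2L)
    stop("training labels contain a single class")

  if (variant$useGraph) {
    if (is.null(graph)) {
      trainIdx <- if (tcfg$transductive) NULL else trainMask
      graph <- buildFusedGraph(matrices, gcfg, trainIdx)
    }
    if (!identical(sampleIds(graph), ids))
      stop("graph sample order does not match matrices")
    Ahat <- convMatrix(graph)
  } else Ahat <- NULL

  Zs <- lapply(matrices, assayValues)
  dims <- vapply(Zs, ncol, integer(1L))
  opts <- list(useAttention = variant$useAttention,
               useSgcn = variant$useSgcn,
               fusionMode = acfg$fusionMode,
               blockActivation = scfg$blockActivation)

  set.seed(seed)
  params <- nnInit(dims, acfg, scfg, opts$useAttention, opts$useSgcn)
  mAdam <- vAdam <- nestedZero(params)
  step <- 0L
  history <- numeric(tcfg$epochs)
  alphaDev <- 0
  n <- length(ids)
  yNum <- ifelse(is.na(y), 0L, y)  # placeholder; masked rows never used
  zWidth <- if (opts$useAttention && opts$fusionMode == "weighted_sum")
    acfg$fusionDim else sum(dims)
  maskWidths <- c(zWidth, rep(scfg$hidden, max(0L, scfg$nLayers - 1L)))

  for (ep in seq_len(tcfg$epochs)) {
    perm <- sample(trainMask)
    batches <- split(perm, ceiling(seq_along(perm) / tcfg$batchSize))
    epLoss <- 0
    for (bt in batches) {
      masks <- NULL
      if (opts$useSgcn && scfg$dropout > 0) {
        keep <- 1 - scfg$dropout
        masks <- lapply(maskWidths, function(w)
          matrix((stats::runif(n * w) < keep) / keep, n, w))
      }
      cache <- nnForward(Zs, Ahat, params, opts, masks)
      if (opts$useAttention)
        alphaDev <- max(alphaDev, max(vapply(cache$attn, function(a)
          abs(sum(a$alpha) - 1), numeric(1L))))
      loss <- nnLoss(cache, params, yNum, bt, tcfg$weightDecay)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep)
      epLoss <- epLoss + loss * length(bt)
      g <- nnBackward(cache, params, opts, yNum, bt, tcfg$weightDecay, Ahat)
      step <- step + 1L
      upd <- adamUpdate(params, g, mAdam, vAdam, tcfg$learningRate, step)
      params <- upd$p; mAdam <- upd$m; vAdam <- upd$v
    }
    history[ep] <- epLoss / length(perm)
  }

  cfg <- list(train = tcfg, graph = gcfg, attention = acfg, sgcn = scfg,
              opts = opts, seed = seed, alphaDeviation = alphaDev,
              graphObject = graph)
  new("SgcnModel", variant = variant$name, params = params, config = cfg,
      featureIds = lapply(matrices, featureIds), sampleIds = ids,
      history = history)
}

#' Predict risk probabilities from a trained model
#'
#' Runs the deterministic forward pass (dropout disabled) over the samples
#' the model was trained on and returns per-sample high-risk
#' probabilities.
#'
#' @param model an [SgcnModel-class].
#' @param matrices the same sample-aligned matrices used at training time
#'   (matched to the model's stored feature IDs).
#' @return data.frame with `sample_id`, `probHighRisk`, `label`.
#' @export
predictRisk <- function(model, matrices) {
  if (model@variant == "sgcnSingleOmics" && length(matrices) > 1L) {
    keep <- vapply(matrices, function(m)
      identical(featureIds(m), model@featureIds[[1L]]), logical(1L))
    matrices <- matrices[which(keep)[1L]]
  }
  stopifnot(length(matrices) == length(model@featureIds))
  Zs <- lapply(seq_along(matrices), function(k) {
    vals <- assayValues(matrices[[k]])
    vals[, model@featureIds[[k]], drop = FALSE]
  })
  opts <- model@config$opts
  Ahat <- if (!is.null(model@config$graphObject))
    convMatrix(model@config$graphObject) else NULL
  cache <- nnForward(Zs, Ahat, model@params, opts, NULL)
  p <- cache$P[, 2L]
  data.frame(sample_id = model@sampleIds, probHighRisk = p,
             label = as.integer(p >= 0.5), row.names = NULL)
}

#' Rank-based AUC
#'
#' Mann-Whitney statistic: the probability that a random positive sample
#' scores above a random negative one, ties counted half.
#'
#' @param p numeric scores.
#' @param y 0/1 labels aligned with `p`.
#' @return AUC in \[0, 1\], or `NA` if either class is absent.
#' @export
aucRank <- function(p, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metricsFromCounts <- function(TP, TN, FP, FN) {
  acc <- (TP + TN) / (TP + TN + FP + FN)
  prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
  rec <- if (TP + FN == 0) 0 else TP / (TP + FN)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Evaluate a trained model on a held-out mask
#'
#' Confusion counts at the 0.5 threshold plus accuracy, precision, recall,
#' F1 and rank-based AUC. If the test mask holds a single class, AUC is
#' reported as `NA` and the other metrics are still computed.
#'
#' @param model an [SgcnModel-class].
#' @param matrices matrices as in [predictRisk()].
#' @param labels named 0/1 vector covering the test samples.
#' @param testMask integer indices of the evaluated samples.
#' @return an [EvaluationReport-class] with a single repeat.
#' @export
evaluateModel <- function(model, matrices, labels, testMask) {
  if (length(testMask) == 0L) stop("empty test mask")
  pred <- predictRisk(model, matrices)
  ids <- pred$sample_id[testMask]
  y <- as.integer(labels[ids])
  p <- pred$probHighRisk[testMask]
  yhat <- as.integer(p >= 0.5)
  TP <- sum(yhat == 1 & y == 1); TN <- sum(yhat == 0 & y == 0)
  FP <- sum(yhat == 1 & y == 0); FN <- sum(yhat == 0 & y == 1)
  mt <- metricsFromCounts(TP, TN, FP, FN)
  evaluationReport(data.frame(
    TP = TP, TN = TN, FP = FP, FN = FN,
    accuracy = mt[["accuracy"]], precision = mt[["precision"]],
    recall = mt[["recall"]], f1 = mt[["f1"]], auc = aucRank(p, y)))
}

evaluationReport <- function(perRepeat) {
  metrics <- c("accuracy", "precision", "recall", "f1", "auc")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m)
      mean(perRepeat[[m]], na.rm = TRUE), numeric(1L)),
    sd = vapply(metrics, function(m)
      if (nrow(perRepeat) > 1L) stats::sd(perRepeat[[m]], na.rm = TRUE)
      else 0, numeric(1L)),
    row.names = NULL)
  new("EvaluationReport", perRepeat = perRepeat, summary = summ)
}

stratifiedSplit <- function(y, trainFraction) {
  idx <- seq_along(y)
  tr <- integer(0)
  for (cls in unique(y)) {
    ic <- idx[y == cls]
    ntr <- max(1L, round(length(ic) * trainFraction))
    tr <- c(tr, sample(ic, ntr))
  }
  sort(tr)
}

#' Repeated stratified hold-out evaluation
#'
#' The evaluation protocol: the labelled samples are split at random into
#' a training and a test fraction, stratified by class; feature selection
#' is refit inside each training split by default (leakage-safe); a model
#' is trained and evaluated; and the repeat-level metrics are aggregated
#' as mean and standard deviation.
#'
#' @param matrices list of preprocessed, sample-aligned
#'   [OmicsMatrix-class] objects covering exactly the labelled samples.
#' @param labels named 0/1 vector covering all samples in `matrices`.
#' @param variant a [variantSpec()].
#' @param nRepeats number of random splits (default 10).
#' @param trainFraction training proportion (default 0.70).
#' @param seed base seed; repeat r uses `seed + r`.
#' @param tcfg,gcfg,acfg,scfg model configuration lists.
#' @param selection `"rlasso"` to refit the hybrid selection inside each
#'   training split, `"none"` to use all supplied features, or
#'   `"wholeCohort"` to fit selection once on all labelled samples
#'   (mimics whole-cohort selection; leaks label information into the
#'   feature set and is off by default).
#' @param lcfg,fcfg selection configurations.
#' @return an [EvaluationReport-class] aggregated over repeats.
#' @export
repeatedHoldout <- function(matrices, labels, variant = variantSpec("dualFusion"),
                            nRepeats = 10, trainFraction = 0.70, seed = 1L,
                            tcfg = trainConfig(), gcfg = graphConfig(),
                            acfg = attentionConfig(), scfg = sgcnConfig(),
                            selection = c("rlasso", "none", "wholeCohort"),
                            lcfg = lassoConfig(), fcfg = forestConfig()) {
  selection <- match.arg(selection)
  stopifnot(nRepeats >= 1)
  ids <- sampleIds(matrices[[1L]])
  y <- as.integer(labels[ids])
  if (anyNA(y)) stop("labels missing for some samples")

  if (selection == "wholeCohort") {
    set.seed(seed)
    matrices <- lapply(matrices, function(m) {
      sel <- rlassoSelect(m, labels, lcfg, fcfg)
      OmicsMatrix(assayValues(m)[, selectedFeatures(sel), drop = FALSE],
                  omicsName(m))
    })
  }

  rows <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    set.seed(seed + r)
    tr <- stratifiedSplit(y, trainFraction)
    te <- setdiff(seq_along(y), tr)
    mats <- matrices
    if (selection == "rlasso") {
      mats <- lapply(matrices, function(m) {
        mtr <- OmicsMatrix(assayValues(m)[tr, , drop = FALSE], omicsName(m))
        sel <- rlassoSelect(mtr, labels, lcfg, fcfg)
        OmicsMatrix(assayValues(m)[, selectedFeatures(sel), drop = FALSE],
                    omicsName(m))
      })
    }
    model <- trainSgcn(mats, labels, tr, variant, tcfg, gcfg, acfg, scfg,
                       seed = seed + r)
    rep1 <- evaluateModel(model, mats, labels, te)
    rows[[r]] <- reportPerRepeat(rep1)
  }
  evaluationReport(do.call(rbind, rows))
}

#' Stratified k-fold cross-validation
#'
#' The alternative evaluation scheme to [repeatedHoldout()]: the labelled
#' samples are partitioned into k class-stratified folds; each fold is
#' held out once while the model trains on the rest. Feature selection is
#' refit inside each training part when `selection = "rlasso"`.
#'
#' @inheritParams repeatedHoldout
#' @param nFolds number of folds (default 5).
#' @return an [EvaluationReport-class] with one row per fold.
#' @export
crossValidate <- function(matrices, labels,
                          variant = variantSpec("dualFusion"),
                          nFolds = 5, seed = 1L,
                          tcfg = trainConfig(), gcfg = graphConfig(),
                          acfg = attentionConfig(), scfg = sgcnConfig(),
                          selection = c("rlasso", "none"),
                          lcfg = lassoConfig(), fcfg = forestConfig()) {
  selection <- match.arg(selection)
  stopifnot(nFolds >= 2)
  ids <- sampleIds(matrices[[1L]])
  y <- as.integer(labels[ids])
  if (anyNA(y)) stop("labels missing for some samples")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ic <- sample(which(y == cls))
    fold[ic] <- rep_len(seq_len(nFolds), length(ic))
  }
  rows <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    te <- which(fold == f)
    tr <- setdiff(seq_along(y), te)
    mats <- matrices
    if (selection == "rlasso") {
      set.seed(seed + f)
      mats <- lapply(matrices, function(m) {
        mtr <- OmicsMatrix(assayValues(m)[tr, , drop = FALSE], omicsName(m))
        sel <- rlassoSelect(mtr, labels, lcfg, fcfg)
        OmicsMatrix(assayValues(m)[, selectedFeatures(sel), drop = FALSE],
                    omicsName(m))
      })
    }
    model <- trainSgcn(mats, labels, tr, variant, tcfg, gcfg, acfg, scfg,
                       seed = seed + f)
    rows[[f]] <- reportPerRepeat(evaluateModel(model, mats, labels, te))
  }
  evaluationReport(do.call(rbind, rows))
}

#' Learned attention weights of a trained model
#'
#' Recomputes the per-omics feature attention vectors from the trained
#' scoring parameters, for interpretation or export.
#'
#' @param model a trained [SgcnModel-class] with attention enabled.
#' @param matrices the sample-aligned matrices used at training time.
#' @param path optional CSV path; if given, a long-format table (omics,
#'   feature, weight) is written there.
#' @return named list of per-omics weight vectors (names = feature IDs).
#' @export
attentionWeightsOf <- function(model, matrices, path = NULL) {
  if (is.null(model@params$attention))
    stop("variant '", model@variant, "' has no attention layer")
  out <- lapply(seq_along(matrices), function(k) {
    vals <- assayValues(matrices[[k]])[, model@featureIds[[k]],
                                       drop = FALSE]
    p <- model@params$attention[[k]]
    a <- attentionWeights(vals, p$W1, p$b, p$W2)
    names(a) <- model@featureIds[[k]]
    a
  })
  names(out) <- vapply(matrices, omicsName, character(1L))
  if (!is.null(path)) {
    df <- do.call(rbind, lapply(names(out), function(nm)
      data.frame(omics = nm, feature = names(out[[nm]]),
                 weight = unname(out[[nm]]))))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Save / load a trained model
#'
#' Checkpoints the full model object (weights, configuration, feature IDs,
#' training history) as a single RDS archive.
#'
#' @param model an [SgcnModel-class].
#' @param path file path for the checkpoint.
#' @return `saveSgcnModel` returns `path` invisibly; `loadSgcnModel`
#'   returns the restored [SgcnModel-class].
#' @export
saveSgcnModel <- function(model, path) {
  stopifnot(is(model, "SgcnModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveSgcnModel
#' @export
loadSgcnModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "SgcnModel")) stop("not an SgcnModel checkpoint")
  model
}

#' Hyperparameter sweep
#'
#' Runs [repeatedHoldout()] once per candidate value of a single
#' hyperparameter, holding everything else fixed, and tabulates the
#' aggregated metrics.
#'
#' @param parameter one of `"kNeighbors"`, `"attentionHiddenUnits"`,
#'   `"nLayers"`.
#' @param values numeric vector (length >= 2, no duplicates) of candidate
#'   values.
#' @param ... arguments forwarded to [repeatedHoldout()].
#' @param gcfg,acfg,scfg base configurations; the swept field is replaced.
#' @return data.frame with one row per value: value, mean and sd of each
#'   metric.
#' @export
sweepParameter <- function(parameter = c("kNeighbors",
                                         "attentionHiddenUnits", "nLayers"),
                           values, ..., gcfg = graphConfig(),
                           acfg = attentionConfig(), scfg = sgcnConfig()) {
  parameter <- match.arg(parameter)
  if (length(values) < 2L) stop("need at least two values to sweep")
  if (anyDuplicated(values)) stop("duplicate sweep values")
  rows <- lapply(values, function(v) {
    g <- gcfg; a <- acfg; s <- scfg
    switch(parameter,
      kNeighbors = { g$kNeighbors <- as.integer(v) },
      attentionHiddenUnits = { a$hiddenUnits <- as.integer(v) },
      nLayers = { s$nLayers <- as.integer(v) })
    rep <- repeatedHoldout(..., gcfg = g, acfg = a, scfg = s)
    s <- reportSummary(rep)
    out <- data.frame(value = v)
    for (i in seq_len(nrow(s))) {
      out[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
      out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
    }
    out
  })
  do.call(rbind, rows)
}
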