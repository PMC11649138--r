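#' LASSO configuration
#'
#' @param lambda either `"cv"` (default: 5-fold cross-validation minimising
#'   squared error, `lambda.min`) or a fixed non-negative penalty.
#' @param maxIterations maximum coordinate-descent iterations.
#' @param tolerance coefficients with absolute value at or below this are
#'   treated as zero (default 1e-8).
#' @return a `lassoConfig` list.
#' @export
lassoConfig <- function(lambda = "cv", maxIterations = 1e5,
                        tolerance = 1e-8) {
  if (!identical(lambda, "cv"))
    stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  structure(list(lambda = lambda, maxIterations = maxIterations,
                 tolerance = tolerance), class = "lassoConfig")
}

#' Random-forest configuration
#'
#' @param nTrees number of trees (default 500).
#' @param topK number of top-importance features to keep (default 100, the
#'   value at which the hybrid selection performs best); truncated with a
#'   warning when it exceeds the feature count.
#' @param seed optional integer seed applied inside the forest fit.
#' @return a `forestConfig` list.
#' @export
forestConfig <- function(nTrees = 500, topK = 100, seed = NULL) {
  stopifnot(nTrees >= 1, topK >= 1)
  structure(list(nTrees = as.integer(nTrees), topK = as.integer(topK),
                 seed = seed), class = "forestConfig")
}

alignLabels <- function(m, labels) {
  ids <- sampleIds(m)
  if (!all(ids %in% names(labels)))
    stop("labels missing for sample(s): ",
         paste(utils::head(setdiff(ids, names(labels)), 5L), collapse = ", "))
  labels[ids]
}

#' LASSO feature selection
#'
#' Fits an L1-penalised least-squares regression of the 0/1 risk label on
#' the (standardised) features and returns the features with nonzero
#' coefficients. The label is treated as a continuous 0/1 response
#' (penalised least squares, gaussian family), not logistic loss.
#'
#' @param m sample-aligned [OmicsMatrix-class] of standardised features.
#' @param labels named 0/1 vector covering the samples of `m`.
#' @param cfg a [lassoConfig()].
#' @return character vector of selected feature IDs.
#' @export
lassoSelect <- function(m, labels, cfg = lassoConfig()) {
  y <- alignLabels(m, labels)
  x <- assayValues(m)
  if (identical(cfg$lambda, "cv")) {
    cvfit <- glmnet::cv.glmnet(x, y, family = "gaussian", nfolds = 5,
                               maxit = cfg$maxIterations)
    lam <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else if (cfg$lambda == 0) {
    # glmnet is unreliable at exactly lambda = 0; use least squares
    beta <- stats::coef(stats::lm.fit(cbind(1, x), y))[-1L]
    return(colnames(x)[!is.na(beta) & abs(beta) > cfg$tolerance])
  } else {
    fit <- glmnet::glmnet(x, y, family = "gaussian",
                          lambda = cfg$lambda, maxit = cfg$maxIterations)
    lam <- cfg$lambda
  }
  if (!fit$jerr == 0)
    stop("LASSO did not converge within ", cfg$maxIterations,
         " iterations (glmnet error ", fit$jerr, ")")
  beta <- as.numeric(stats::coef(fit, s = lam))[-1L]  # drop intercept
  colnames(x)[abs(beta) > cfg$tolerance]
}

#' Random-forest permutation importance and top-K ranking
#'
#' Grows a classification forest on the 0/1 labels and ranks features by
#' out-of-bag permutation importance: the mean over trees of the drop in
#' out-of-bag classification accuracy after permuting the feature
#' (unscaled mean decrease in accuracy). Ties are broken by feature-ID
#' order so the ranking is deterministic under a fixed seed.
#'
#' @inheritParams lassoSelect
#' @param cfg a [forestConfig()].
#' @return list with `topFeatures` (IDs, decreasing importance, length
#'   `min(topK, nFeatures)`) and `importances` (named vector, all features).
#' @export
forestTopK <- function(m, labels, cfg = forestConfig()) {
  y <- factor(alignLabels(m, labels), levels = c(0, 1))
  x <- assayValues(m)
  if (cfg$nTrees < 1) stop("nTrees must be >= 1")
  k <- cfg$topK
  if (k > ncol(x)) {
    warning("topK (", k, ") exceeds feature count (", ncol(x),
            "); truncating")
    k <- ncol(x)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rf <- randomForest::randomForest(x, y, ntree = cfg$nTrees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  names(imp) <- colnames(x)
  ord <- order(-imp, names(imp), method = "radix")
  list(topFeatures = names(imp)[ord][seq_len(k)], importances = imp)
}

#' Hybrid LASSO / random-forest feature selection
#'
#' Selects, per omics layer, the union of the LASSO-retained features and
#' the top-K features by random-forest out-of-bag permutation importance.
#' The forest ranking supplements features the L1 penalty discards, so the
#' union's recall of informative features is never below that of the LASSO
#' alone.
#'
#' @inheritParams lassoSelect
#' @param lcfg a [lassoConfig()].
#' @param fcfg a [forestConfig()].
#' @return a [SelectionResult-class].
#' @export
rlassoSelect <- function(m, labels, lcfg = lassoConfig(),
                         fcfg = forestConfig()) {
  lassoFeats <- lassoSelect(m, labels, lcfg)
  forest <- forestTopK(m, labels, fcfg)
  sel <- union(lassoFeats, forest$topFeatures)
  new("SelectionResult", omicsName = omicsName(m),
      lassoFeatures = lassoFeats, forestFeatures = forest$topFeatures,
      selected = sel, importances = forest$importances)
}

#' Serialise a SelectionResult to JSON
#'
#' @param x a [SelectionResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSelectionResult <- function(x, path) {
  jsonlite::write_json(
    list(omics = x@omicsName, lasso = x@lassoFeatures,
         forest = x@forestFeatures, selected = x@selected,
         importances = as.list(x@importances)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
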