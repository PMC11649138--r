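#' @import methods
NULL

#' OmicsMatrix: one omics layer
#'
#' A single omics layer holding an n x d numeric matrix of measurements,
#' rows are samples and columns are features. Missing entries are `NA`.
#' Sample and feature identifiers live in the matrix dimnames and must be
#' unique; all alignment across layers is done by sample identifier, never
#' by row position.
#'
#' @slot omicsName single character label for the layer (e.g. "mRNA").
#' @slot assay numeric matrix, samples x features, with complete dimnames.
#'
#' @seealso [OmicsMatrix()] for construction, [readOmicsMatrix()] to parse
#'   a delimited file.
#' @export
setClass("OmicsMatrix",
  representation(omicsName = "character", assay = "matrix"))

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  a <- object@assay
  if (length(object@omicsName) != 1L || is.na(object@omicsName))
    msg <- c(msg, "omicsName must be a single non-NA string")
  if (!is.numeric(a))
    msg <- c(msg, "assay must be numeric")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "assay must have sample (row) and feature (column) names")
  else {
    dupS <- unique(rownames(a)[duplicated(rownames(a))])
    dupF <- unique(colnames(a)[duplicated(colnames(a))])
    if (length(dupS))
      msg <- c(msg, paste0("duplicate sample IDs: ",
                           paste(dupS, collapse = ", ")))
    if (length(dupF))
      msg <- c(msg, paste0("duplicate feature IDs: ",
                           paste(dupF, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix (samples x features) with dimnames, or an
#'   object coercible to one.
#' @param omicsName character label for the omics layer.
#' @param sampleIds,featureIds optional identifier vectors overriding the
#'   dimnames of `values`.
#' @return an [OmicsMatrix-class] object.
#' @examples
#' m <- OmicsMatrix(matrix(rnorm(6), 3, 2,
#'                  dimnames = list(paste0("S", 1:3), c("g1", "g2"))), "mRNA")
#' nSamples(m)
#' @export
OmicsMatrix <- function(values, omicsName = "omics",
                        sampleIds = NULL, featureIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(sampleIds)) rownames(values) <- as.character(sampleIds)
  if (!is.null(featureIds)) colnames(values) <- as.character(featureIds)
  new("OmicsMatrix", omicsName = omicsName, assay = values)
}

#' SampleGraph: patient similarity graph
#'
#' Symmetric weighted adjacency over n samples with zero diagonal and
#' entries in \[0, 1\], as produced by the exponential-kernel kNN builder
#' and by graph fusion.
#'
#' @slot sampleIds ordered sample identifiers.
#' @slot adjacency n x n symmetric numeric matrix.
#' @seealso [buildKnnGraph()], [fuseGraphs()], [normalizeAdjacency()]
#' @export
setClass("SampleGraph",
  representation(sampleIds = "character", adjacency = "matrix"))

setValidity("SampleGraph", function(object) {
  A <- object@adjacency
  n <- length(object@sampleIds)
  msg <- character()
  if (!is.numeric(A) || nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency must be an n x n numeric matrix")
  else {
    if (max(abs(A - t(A))) > 1e-10) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
    if (min(A) < -1e-12 || max(A) > 1 + 1e-12)
      msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicate sample IDs")
  if (length(msg)) msg else TRUE
})

#' NormalizedGraph: graph-convolution operator
#'
#' The symmetric degree-normalised, self-looped adjacency
#' \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}} used as the
#' propagation operator in graph convolution. Its spectrum lies in
#' \[-1, 1\].
#'
#' @slot sampleIds ordered sample identifiers.
#' @slot convMatrix n x n symmetric numeric matrix.
#' @export
setClass("NormalizedGraph",
  representation(sampleIds = "character", convMatrix = "matrix"))

setValidity("NormalizedGraph", function(object) {
  M <- object@convMatrix
  n <- length(object@sampleIds)
  if (!is.numeric(M) || nrow(M) != n || ncol(M) != n)
    return("convMatrix must be an n x n numeric matrix")
  if (max(abs(M - t(M))) > 1e-9) return("convMatrix must be symmetric")
  TRUE
})

#' SelectionResult: hybrid LASSO / random-forest feature selection
#'
#' Result of the hybrid selection for one omics layer: the features with
#' nonzero LASSO coefficients, the top-K features by random-forest
#' out-of-bag permutation importance, and their union.
#'
#' @slot omicsName omics layer label.
#' @slot lassoFeatures feature IDs retained by the LASSO fit.
#' @slot forestFeatures top-K feature IDs, ordered by decreasing importance.
#' @slot selected union of the two sets.
#' @slot importances named numeric vector of permutation importances for all
#'   features.
#' @seealso [rlassoSelect()]
#' @export
setClass("SelectionResult",
  representation(omicsName = "character", lassoFeatures = "character",
                 forestFeatures = "character", selected = "character",
                 importances = "numeric"))

setValidity("SelectionResult", function(object) {
  if (!setequal(object@selected,
                union(object@lassoFeatures, object@forestFeatures)))
    return("selected must equal the union of LASSO and forest features")
  TRUE
})

#' SgcnModel: trained dual-fusion stacked-GCN model
#'
#' Holds the learned parameters of the attention scoring networks,
#' per-omics projections, stacked graph-convolution layers and classifier
#' head, together with the configuration, variant, the feature IDs each
#' omics layer was trained on, and the per-epoch training loss.
#'
#' @slot variant variant name (see [variantSpec()]).
#' @slot params list of parameter matrices/vectors.
#' @slot config list of configuration values used at training time.
#' @slot featureIds list (per omics) of feature IDs the model consumes.
#' @slot sampleIds samples the transductive graph was built over.
#' @slot history numeric vector of mean training loss per epoch.
#' @export
setClass("SgcnModel",
  representation(variant = "character", params = "list", config = "list",
                 featureIds = "list", sampleIds = "character",
                 history = "numeric"))

#' EvaluationReport: classification metrics over hold-out repeats
#'
#' Confusion counts and derived metrics (accuracy, precision, recall, F1,
#' AUC) for each repeat of the evaluation protocol, plus mean and standard
#' deviation across repeats.
#'
#' @slot perRepeat data.frame with one row per repeat: TP, TN, FP, FN,
#'   accuracy, precision, recall, f1, auc.
#' @slot summary data.frame with columns metric, mean, sd.
#' @export
setClass("EvaluationReport",
  representation(perRepeat = "data.frame", summary = "data.frame"))

setValidity("EvaluationReport", function(object) {
  need <- c("TP", "TN", "FP", "FN", "accuracy", "precision", "recall",
            "f1", "auc")
  if (!all(need %in% colnames(object@perRepeat)))
    return(paste("perRepeat must contain columns:",
                 paste(need, collapse = ", ")))
  TRUE
})
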