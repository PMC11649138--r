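#' @rdname OmicsMatrix-class
#' @param x,object an object.
#' @export
setGeneric("omicsName", function(x) standardGeneric("omicsName"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("assayValues", function(x) standardGeneric("assayValues"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname SampleGraph-class
#' @param x an object.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname NormalizedGraph-class
#' @param x an object.
#' @export
setGeneric("convMatrix", function(x) standardGeneric("convMatrix"))

#' @rdname SelectionResult-class
#' @param x an object.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

setMethod("omicsName", "OmicsMatrix", function(x) x@omicsName)
setMethod("sampleIds", "OmicsMatrix", function(x) rownames(x@assay))
setMethod("featureIds", "OmicsMatrix", function(x) colnames(x@assay))
setMethod("assayValues", "OmicsMatrix", function(x) x@assay)
setMethod("nSamples", "OmicsMatrix", function(x) nrow(x@assay))
setMethod("nFeatures", "OmicsMatrix", function(x) ncol(x@assay))
setMethod("dim", "OmicsMatrix", function(x) dim(x@assay))

setMethod("sampleIds", "SampleGraph", function(x) x@sampleIds)
setMethod("adjacency", "SampleGraph", function(x) x@adjacency)
setMethod("sampleIds", "NormalizedGraph", function(x) x@sampleIds)
setMethod("convMatrix", "NormalizedGraph", function(x) x@convMatrix)

setMethod("omicsName", "SelectionResult", function(x) x@omicsName)
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

setMethod("show", "OmicsMatrix", function(object) {
  cat("OmicsMatrix '", object@omicsName, "': ",
      nrow(object@assay), " samples x ", ncol(object@assay), " features; ",
      sum(is.na(object@assay)), " missing\n", sep = "")
})

setMethod("show", "SampleGraph", function(object) {
  A <- object@adjacency
  cat("SampleGraph: ", length(object@sampleIds), " samples, ",
      sum(A[upper.tri(A)] > 0), " weighted edges\n", sep = "")
})

setMethod("show", "NormalizedGraph", function(object) {
  cat("NormalizedGraph (convolution operator): ",
      length(object@sampleIds), " samples\n", sep = "")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult '", object@omicsName, "': ",
      length(object@lassoFeatures), " LASSO + ",
      length(object@forestFeatures), " forest top-K -> ",
      length(object@selected), " selected\n", sep = "")
})

setMethod("show", "SgcnModel", function(object) {
  cat("SgcnModel variant '", object@variant, "': ",
      length(object@featureIds), " omics layer(s), ",
      object@config$sgcn$nLayers, " graph-convolution layer(s), trained ",
      length(object@history), " epoch(s)\n", sep = "")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport over", nrow(object@perRepeat), "repeat(s):\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
})

#' @rdname EvaluationReport-class
#' @param x an `EvaluationReport`.
#' @return `reportSummary` returns the metric/mean/sd data.frame;
#'   `reportPerRepeat` the per-repeat metric table.
#' @export
reportSummary <- function(x) x@summary

#' @rdname EvaluationReport-class
#' @export
reportPerRepeat <- function(x) x@perRepeat
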