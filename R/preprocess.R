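#' Preprocessing configuration
#'
#' Settings for the four-step preprocessing of one omics layer. Variances
#' use the population convention (divide by n) throughout the package.
#'
#' @param missingFractionMax features with a missing fraction strictly
#'   greater than this are dropped (default 0.20; a feature missing exactly
#'   20 percent is kept).
#' @param varianceThreshold features with population variance strictly
#'   greater than this are retained. Conventional starting points per layer:
#'   mRNA 7, DNA methylation 0.02, CNV 0.1, miRNA 0 (no filter).
#' @param zerosAsMissing if `TRUE`, exact zeros are recoded as missing before
#'   filtering, as is common for expression-like layers where zero means
#'   "not measured"; leave `FALSE` for CNV-like scales where 0 is a value.
#' @return a `preprocessConfig` list.
#' @export
preprocessConfig <- function(missingFractionMax = 0.20,
                             varianceThreshold = 0,
                             zerosAsMissing = FALSE) {
  stopifnot(missingFractionMax >= 0, missingFractionMax <= 1,
            varianceThreshold >= 0)
  structure(list(missingFractionMax = missingFractionMax,
                 varianceThreshold = varianceThreshold,
                 zerosAsMissing = zerosAsMissing),
            class = "preprocessConfig")
}

# population variance, per column
colVarPop <- function(x) {
  mu <- colMeans(x)
  colMeans(x^2) - mu^2
}

#' Align omics layers and clinical table to their common samples
#'
#' Step 1 of preprocessing: every returned matrix is restricted to the
#' sorted intersection of sample IDs across all layers and the clinical
#' table, in identical order. Alignment is by ID, never by row position.
#'
#' @param matrices list of [OmicsMatrix-class] objects.
#' @param clinical optional clinical data.frame; if supplied, its samples
#'   join the intersection.
#' @return list of OmicsMatrix objects with identical sample order.
#' @export
intersectSamples <- function(matrices, clinical = NULL) {
  stopifnot(length(matrices) >= 1L)
  common <- Reduce(intersect, lapply(matrices, sampleIds))
  if (!is.null(clinical))
    common <- intersect(common, validateClinical(clinical)$sample_id)
  common <- sort(common)
  if (length(common) == 0L)
    stop("empty intersection of sample IDs across inputs")
  lapply(matrices, function(m)
    OmicsMatrix(assayValues(m)[common, , drop = FALSE], omicsName(m)))
}

#' Filter high-missingness features and impute the rest by the median
#'
#' Step 2 of preprocessing. If configured, exact zeros become missing
#' first. Features whose missing fraction strictly exceeds
#' `missingFractionMax` are dropped; remaining missing entries are replaced
#' by the feature's median over observed values. Features that end up with
#' no observed value at all are dropped with a warning.
#'
#' @param m an [OmicsMatrix-class].
#' @param cfg a [preprocessConfig()].
#' @return an imputed [OmicsMatrix-class] with no missing values.
#' @export
filterAndImpute <- function(m, cfg = preprocessConfig()) {
  vals <- assayValues(m)
  if (isTRUE(cfg$zerosAsMissing)) vals[vals == 0] <- NA_real_
  frac <- colMeans(is.na(vals))
  keep <- frac <= cfg$missingFractionMax
  allMissing <- frac == 1
  if (any(keep & allMissing)) {
    warning("dropping feature(s) with all values missing: ",
            paste(colnames(vals)[keep & allMissing], collapse = ", "))
    keep <- keep & !allMissing
  }
  vals <- vals[, keep, drop = FALSE]
  for (j in which(colSums(is.na(vals)) > 0L)) {
    med <- stats::median(vals[, j], na.rm = TRUE)
    vals[is.na(vals[, j]), j] <- med
  }
  OmicsMatrix(vals, omicsName(m))
}

#' Retain features above a variance threshold
#'
#' Step 3 of preprocessing: keeps features whose population variance across
#' all samples is strictly greater than `threshold`.
#'
#' @param m an [OmicsMatrix-class] with no missing values.
#' @param threshold non-negative variance threshold.
#' @return filtered [OmicsMatrix-class].
#' @export
varianceFilter <- function(m, threshold = 0) {
  stopifnot(threshold >= 0)
  vals <- assayValues(m)
  if (anyNA(vals)) stop("varianceFilter requires imputed (complete) values")
  keep <- colVarPop(vals) > threshold
  if (!any(keep))
    stop("no features exceed variance threshold ", threshold,
         "; lower the threshold")
  OmicsMatrix(vals[, keep, drop = FALSE], omicsName(m))
}

#' Z-score normalise features
#'
#' Step 4 of preprocessing: each feature column is centred and scaled to
#' population variance 1.
#'
#' @param m an [OmicsMatrix-class] with no missing values and no constant
#'   features (apply [varianceFilter()] first).
#' @return standardised [OmicsMatrix-class].
#' @export
zscoreNormalize <- function(m) {
  vals <- assayValues(m)
  if (anyNA(vals)) stop("zscoreNormalize requires complete values")
  v <- colVarPop(vals)
  if (any(v <= 0))
    stop("zero-variance feature(s): ",
         paste(colnames(vals)[v <= 0], collapse = ", "))
  vals <- sweep(vals, 2L, colMeans(vals), "-")
  vals <- sweep(vals, 2L, sqrt(v), "/")
  OmicsMatrix(vals, omicsName(m))
}

#' Run the full four-step preprocessing over several omics layers
#'
#' Sample intersection, missingness filtering with median imputation,
#' variance thresholding, then z-score normalisation, in that fixed order.
#' Feature counts are non-increasing at every step and the sample count is
#' constant after intersection.
#'
#' @param matrices list of [OmicsMatrix-class] objects.
#' @param clinical optional clinical data.frame joining the intersection.
#' @param configs a single [preprocessConfig()] applied to all layers, or a
#'   list of one config per layer.
#' @return list of preprocessed OmicsMatrix objects, sample-aligned.
#' @export
preprocessPipeline <- function(matrices, clinical = NULL,
                               configs = preprocessConfig()) {
  if (inherits(configs, "preprocessConfig"))
    configs <- rep(list(configs), length(matrices))
  stopifnot(length(configs) == length(matrices))
  matrices <- intersectSamples(matrices, clinical)
  out <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    m <- filterAndImpute(matrices[[i]], configs[[i]])
    m <- varianceFilter(m, configs[[i]]$varianceThreshold)
    out[[i]] <- zscoreNormalize(m)
  }
  names(out) <- vapply(out, omicsName, character(1L))
  out
}
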