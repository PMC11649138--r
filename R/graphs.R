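#' Graph construction configuration
#'
#' @param kNeighbors number of nearest neighbours per sample (default 12,
#'   inside the 10-16 band where held-out F1 is flat and highest).
#' @param mu positive bandwidth multiplier of the exponential kernel
#'   (default 0.5).
#' @return a `graphConfig` list. The kernel scale \eqn{\delta^2} is always
#'   the median of squared Euclidean distances over unordered distinct
#'   sample pairs (self-pairs excluded).
#' @export
graphConfig <- function(kNeighbors = 12, mu = 0.5) {
  stopifnot(kNeighbors >= 1, mu > 0)
  structure(list(kNeighbors = as.integer(kNeighbors), mu = mu),
            class = "graphConfig")
}

#' Build a kNN patient-similarity graph with the exponential kernel
#'
#' For samples \eqn{x_i} with squared Euclidean distances
#' \eqn{\rho^2(x_i,x_j)}, the directed weight to each of the k nearest
#' neighbours of i is \eqn{\exp(-\rho^2/(\mu\,\delta^2))}, zero otherwise,
#' where \eqn{\delta^2} is the median squared distance over all distinct
#' unordered pairs. Neighbour ties at the k-th position are resolved toward
#' the lower sample ID. The directed relation is symmetrised as
#' \eqn{(W + W^T)/2} with a zero diagonal.
#'
#' @param m sample-aligned [OmicsMatrix-class] with no missing values.
#' @param cfg a [graphConfig()]; requires `kNeighbors < nSamples(m)`.
#' @return a [SampleGraph-class].
#' @export
buildKnnGraph <- function(m, cfg = graphConfig()) {
  x <- assayValues(m)
  n <- nrow(x)
  k <- cfg$kNeighbors
  if (anyNA(x)) stop("graph construction requires complete values")
  if (n <= k) stop("need nSamples > kNeighbors (", n, " <= ", k, ")")
  d2 <- as.matrix(stats::dist(x))^2
  delta2 <- stats::median(d2[upper.tri(d2)])
  if (delta2 == 0) stop("degenerate geometry: all samples identical")
  kern <- exp(-d2 / (cfg$mu * delta2))
  W <- matrix(0, n, n)
  ids <- rownames(x)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], ids, method = "radix")
    ord <- ord[ord != i]
    nb <- ord[seq_len(k)]
    W[i, nb] <- kern[i, nb]
  }
  A <- (W + t(W)) / 2
  diag(A) <- 0
  dimnames(A) <- list(ids, ids)
  new("SampleGraph", sampleIds = ids, adjacency = A)
}

#' Fuse per-omics graphs by averaging
#'
#' Elementwise mean of the adjacency matrices of graphs sharing an
#' identical sample order.
#'
#' @param graphs list of [SampleGraph-class] objects.
#' @return fused [SampleGraph-class].
#' @export
fuseGraphs <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  ids <- sampleIds(graphs[[1L]])
  for (g in graphs)
    if (!identical(sampleIds(g), ids))
      stop("graphs have mismatched sample orders")
  A <- Reduce(`+`, lapply(graphs, adjacency)) / length(graphs)
  new("SampleGraph", sampleIds = ids, adjacency = A)
}

#' Symmetric normalisation of an adjacency into a convolution operator
#'
#' Adds self-loops and degree-normalises:
#' \eqn{\tilde A = A + I_n}, \eqn{\tilde d_i = \sum_j \tilde A_{ij}},
#' \eqn{\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}}. With the
#' self-loop every \eqn{\tilde d_i \ge 1}, so the operation is always
#' defined, and the spectrum of \eqn{\hat A} lies in \[-1, 1\].
#'
#' @param g a [SampleGraph-class] (symmetric, non-negative adjacency).
#' @return a [NormalizedGraph-class].
#' @export
normalizeAdjacency <- function(g) {
  A <- adjacency(g)
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  Ahat <- At * (dinv %o% dinv)
  Ahat <- (Ahat + t(Ahat)) / 2  # remove rounding asymmetry
  new("NormalizedGraph", sampleIds = sampleIds(g), convMatrix = Ahat)
}

#' Write a graph as a dense CSV matrix
#'
#' Square adjacency with sample IDs as row and column names.
#'
#' @param g a [SampleGraph-class] or [NormalizedGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphMatrix <- function(g, path) {
  M <- if (is(g, "NormalizedGraph")) convMatrix(g) else adjacency(g)
  dimnames(M) <- list(sampleIds(g), sampleIds(g))
  utils::write.csv(M, path, quote = FALSE)
  invisible(path)
}

#' Write a graph as a TSV edge list
#'
#' Emits one `i<TAB>j<TAB>weight` row per nonzero upper-triangle entry.
#'
#' @param g a [SampleGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  A <- adjacency(g)
  ids <- sampleIds(g)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(i = ids[idx[, 1L]], j = ids[idx[, 2L]],
                   weight = A[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
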