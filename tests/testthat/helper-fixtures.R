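# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

makeOmics <- function(n = 5, d = 3, seed = 1, name = "mRNA",
                      ids = sprintf("S%02d", seq_len(n)),
                      feats = sprintf("%s_f%d", name, seq_len(d))) {
  set.seed(seed)
  OmicsMatrix(matrix(rnorm(n * d), n, d, dimnames = list(ids, feats)), name)
}

# independent brute-force oracle for the exponential-kernel kNN graph:
# enumerate all pairwise squared distances, take the median, sort each
# row's neighbours, apply the kernel, symmetrise
bruteKnnGraph <- function(x, k, mu) {
  n <- nrow(x)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((x[i, ] - x[j, ])^2)
  pairs <- d2[upper.tri(d2)]
  delta2 <- stats::median(pairs)
  W <- matrix(0, n, n)
  ids <- rownames(x)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d2[i, others], ids[others], method = "radix")]
    for (j in ord[seq_len(k)]) W[i, j] <- exp(-d2[i, j] / (mu * delta2))
  }
  A <- (W + t(W)) / 2
  diag(A) <- 0
  A
}

# independent hand-rolled product-limit estimator (risk-set tally)
bruteKM <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    atRisk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# independent hand-rolled two-group log-rank chi-square
bruteLogrank <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ut <- sort(unique(times[events == 1]))
  oe <- 0; vv <- 0
  for (tt in ut) {
    n1 <- sum(times >= tt & grp == 1)
    n2 <- sum(times >= tt & grp == 2)
    n <- n1 + n2
    d <- sum(times == tt & events == 1)
    o1 <- sum(times == tt & events == 1 & grp == 1)
    oe <- oe + (o1 - d * n1 / n)
    if (n > 1) vv <- vv + d * n1 * n2 * (n - d) / (n^2 * (n - 1))
  }
  oe^2 / vv
}

# small fully trainable dataset: 2 omics, clear 2-class signal, no missing
smallDataset <- function(seed = 3, n = 60) {
  generateMultiOmics(syntheticConfig(
    nSamples = n, omicsDims = c(a = 20, b = 15), informativePerOmics = 5,
    effectSize = 2, missingRate = 0, seed = seed))
}

zscoreAll <- function(matrices)
  lapply(matrices, function(m) zscoreNormalize(varianceFilter(m, 0)))
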