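# Seeded generator of multi-omics datasets with the structure the model
# assumes: several omics blocks of differing width measured on common
# samples, two latent risk classes shifting a subset of informative
# features, cross-omics shared latent factors inducing correlated
# structure, class-dependent exponential survival with calibrated
# independent censoring, and optional missingness.

#' Synthetic multi-omics configuration
#'
#' @param nSamples number of samples (default 300).
#' @param classProportion probability of the high-risk class (default 0.5).
#' @param omicsDims feature counts per omics block (default
#'   `c(200, 150, 60, 100)`, four blocks of differing width).
#' @param informativePerOmics number of class-informative features per
#'   block; scalar (recycled) or vector per block (default 15).
#' @param effectSize mean shift between classes on informative features, in
#'   noise-sd units (default 1.5; classes sit at +/- effectSize/2).
#' @param nSharedFactors number of cross-omics latent factors (default 3).
#' @param factorLoadingSd standard deviation of the factor loadings
#'   (default 0.3: visible correlated structure without swamping the class
#'   signal).
#' @param noiseSd independent noise standard deviation (default 1.0).
#' @param hazardRatio multiplicative hazard of the high-risk class
#'   (default 3.0).
#' @param censoringRate target fraction of censored samples (default 0.3);
#'   the censoring hazard is solved to hit this in expectation.
#' @param missingRate fraction of entries masked as missing (default 0.05).
#' @param signalMode placement of the class signal: `"disjoint_across_omics"`
#'   (default; every block carries a private informative subset, so no
#'   single layer holds the full signal), `"all_omics"` (every block
#'   carries the class signal; identical placement, named for the study
#'   design), or `"one_omics_only"` (all informative features concentrated
#'   in the first block).
#' @param seed integer seed; all draws come from this seeded generator.
#' @return a `syntheticConfig` list.
#' @export
syntheticConfig <- function(nSamples = 300, classProportion = 0.5,
                            omicsDims = c(mRNA = 200, methylation = 150,
                                          miRNA = 60, CNV = 100),
                            informativePerOmics = 15, effectSize = 1.5,
                            nSharedFactors = 3, factorLoadingSd = 0.3,
                            noiseSd = 1.0, hazardRatio = 3.0,
                            censoringRate = 0.3, missingRate = 0.05,
                            signalMode = c("disjoint_across_omics",
                                           "all_omics", "one_omics_only"),
                            seed = 1L) {
  signalMode <- match.arg(signalMode)
  stopifnot(nSamples >= 2, classProportion > 0, classProportion < 1,
            all(omicsDims >= 1), effectSize >= 0, nSharedFactors >= 0,
            noiseSd > 0, hazardRatio > 0, censoringRate >= 0,
            censoringRate < 1, missingRate >= 0, missingRate < 1)
  if (is.null(names(omicsDims)))
    names(omicsDims) <- paste0("omics", seq_along(omicsDims))
  informativePerOmics <- rep_len(informativePerOmics, length(omicsDims))
  if (any(informativePerOmics > omicsDims))
    stop("informativePerOmics exceeds omics dimension")
  structure(list(nSamples = as.integer(nSamples),
                 classProportion = classProportion,
                 omicsDims = omicsDims,
                 informativePerOmics = as.integer(informativePerOmics),
                 effectSize = effectSize,
                 nSharedFactors = as.integer(nSharedFactors),
                 factorLoadingSd = factorLoadingSd, noiseSd = noiseSd,
                 hazardRatio = hazardRatio, censoringRate = censoringRate,
                 missingRate = missingRate, signalMode = signalMode,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Re-place the class signal across omics blocks
#'
#' Returns a copy of the configuration with the informative features placed
#' according to `mode`: `"one_omics_only"` concentrates them in the first
#' block (other blocks carry none), while `"all_omics"` and
#' `"disjoint_across_omics"` give every block an informative subset —
#' subsets in different blocks are disjoint by construction, so no single
#' layer holds the full signal.
#'
#' @param cfg a [syntheticConfig()].
#' @param mode signal placement mode.
#' @return modified `syntheticConfig`.
#' @export
splitSignal <- function(cfg, mode = c("all_omics", "one_omics_only",
                                      "disjoint_across_omics")) {
  mode <- match.arg(mode)
  m <- cfg$informativePerOmics
  if (mode == "one_omics_only") {
    total <- min(sum(m), cfg$omicsDims[1L])
    cfg$informativePerOmics <- c(total, rep(0L, length(m) - 1L))
  } else {
    base <- max(m[m > 0], 15L)
    cfg$informativePerOmics <- pmin(rep(base, length(m)), cfg$omicsDims)
  }
  cfg$signalMode <- mode
  cfg
}

# censoring hazard giving the target expected censoring fraction:
# with T ~ Exp(lambda_c) and C ~ Exp(r), P(C < T | class c) = r/(r+lambda_c)
solveCensoringRate <- function(lambda0, hr, pClass1, target) {
  if (target == 0) return(0)
  f <- function(r)
    (1 - pClass1) * r / (r + lambda0) +
      pClass1 * r / (r + lambda0 * hr) - target
  stats::uniroot(f, lower = 1e-12, upper = lambda0 * hr * 1e6,
                 tol = 1e-12)$root
}

#' Generate a synthetic multi-omics dataset
#'
#' Per sample: a latent class `c` is drawn; shared latent factors
#' `u ~ N(0, I)` feed every block through Gaussian loadings; feature j of
#' block k is `mu_jc + loadings . u + noise`, where `mu_jc` is
#' +/- effectSize/2 on that block's informative features and 0 elsewhere.
#' Survival time is exponential with rate `lambda0 * hazardRatio^c`
#' (baseline median 3 years for the low-risk class); censoring is an
#' independent exponential calibrated to the target censoring fraction.
#' Entries are masked missing at `missingRate`.
#'
#' @param cfg a [syntheticConfig()].
#' @return list with `matrices` (list of [OmicsMatrix-class]), `clinical`
#'   (data.frame: sample_id, survival_time, event), `labels` (named 0/1
#'   true-class vector) and `truth` (informative feature IDs per block,
#'   factor loadings, survival rates, config echo).
#' @export
generateMultiOmics <- function(cfg = syntheticConfig()) {
  set.seed(cfg$seed)
  n <- cfg$nSamples
  ids <- sprintf("S%04d", seq_len(n))
  cls <- stats::rbinom(n, 1L, cfg$classProportion)
  names(cls) <- ids
  u <- matrix(stats::rnorm(n * cfg$nSharedFactors), n, cfg$nSharedFactors)

  matrices <- vector("list", length(cfg$omicsDims))
  informative <- vector("list", length(cfg$omicsDims))
  loadings <- vector("list", length(cfg$omicsDims))
  for (k in seq_along(cfg$omicsDims)) {
    dk <- cfg$omicsDims[k]
    nm <- names(cfg$omicsDims)[k]
    feats <- sprintf("%s_f%03d", nm, seq_len(dk))
    Lk <- matrix(stats::rnorm(cfg$nSharedFactors * dk, 0,
                              cfg$factorLoadingSd),
                 cfg$nSharedFactors, dk)
    vals <- u %*% Lk + matrix(stats::rnorm(n * dk, 0, cfg$noiseSd), n, dk)
    mk <- cfg$informativePerOmics[k]
    inf <- if (mk > 0) sort(sample.int(dk, mk)) else integer(0)
    if (mk > 0) {
      shift <- ifelse(cls == 1L, cfg$effectSize / 2, -cfg$effectSize / 2)
      vals[, inf] <- vals[, inf] + shift
    }
    if (cfg$missingRate > 0) {
      mask <- stats::runif(n * dk) < cfg$missingRate
      vals[mask] <- NA_real_
    }
    dimnames(vals) <- list(ids, feats)
    matrices[[k]] <- OmicsMatrix(vals, nm)
    informative[[k]] <- feats[inf]
    loadings[[k]] <- Lk
  }
  names(matrices) <- names(informative) <- names(loadings) <-
    names(cfg$omicsDims)

  lambda0 <- log(2) / 1095  # low-risk median survival: 3 years
  rates <- lambda0 * cfg$hazardRatio^cls
  tEvent <- stats::rexp(n, rates)
  censRate <- solveCensoringRate(lambda0, cfg$hazardRatio,
                                 cfg$classProportion, cfg$censoringRate)
  tCens <- if (censRate > 0) stats::rexp(n, censRate) else rep(Inf, n)
  clinical <- data.frame(sample_id = ids,
                         survival_time = pmin(tEvent, tCens),
                         event = as.integer(tEvent <= tCens))

  list(matrices = matrices, clinical = clinical, labels = cls,
       truth = list(informative = informative, loadings = loadings,
                    factors = u, lambda0 = lambda0,
                    censoringHazard = censRate, config = cfg))
}

#' Bayes-optimal accuracy of the synthetic generative model
#'
#' With Gaussian blocks sharing the factor covariance
#' \eqn{\Sigma = L^T L + \sigma^2 I} and class means \eqn{\pm \Delta/2} on
#' the informative features, the Bayes rule is linear discriminant
#' analysis with error \eqn{\Phi(-\sqrt{m}/2)},
#' \eqn{m = \delta^T \Sigma^{-1} \delta} the Mahalanobis separation. Used
#' as an analytic reference for what any classifier can achieve on these
#' data.
#'
#' @param dataset output of [generateMultiOmics()].
#' @param omicsIdx which blocks to include (default all).
#' @return list with `separation` (Mahalanobis distance) and `accuracy`
#'   (Bayes accuracy at equal priors).
#' @export
bayesAccuracy <- function(dataset, omicsIdx = NULL) {
  cfg <- dataset$truth$config
  if (is.null(omicsIdx)) omicsIdx <- seq_along(cfg$omicsDims)
  m2 <- 0
  for (k in omicsIdx) {
    Lk <- dataset$truth$loadings[[k]]
    dk <- ncol(Lk)
    Sigma <- crossprod(Lk) + diag(cfg$noiseSd^2, dk)
    delta <- numeric(dk)
    infIdx <- match(dataset$truth$informative[[k]],
                    featureIds(dataset$matrices[[k]]))
    delta[infIdx] <- cfg$effectSize
    m2 <- m2 + as.numeric(delta %*% solve(Sigma, delta))
  }
  list(separation = sqrt(m2), accuracy = stats::pnorm(sqrt(m2) / 2))
}

#' Write a synthetic dataset to disk
#'
#' One matrix CSV per omics block, a clinical CSV, and a truth JSON
#' (labels, informative feature IDs, config echo).
#'
#' @param dataset output of [generateMultiOmics()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in dataset$matrices)
    writeOmicsMatrix(m, file.path(dir, paste0(omicsName(m), ".csv")))
  utils::write.csv(dataset$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- dataset$truth$config
  jsonlite::write_json(
    list(labels = as.list(dataset$labels),
         informative = dataset$truth$informative,
         config = unclass(cfg)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
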