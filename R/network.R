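# Dual-fusion network core: per-omics feature attention, learnable
# projection fusion, stacked graph-convolution blocks, relu/softmax head.
# Forward and backward passes are written out explicitly (dense matrix
# algebra); gradients are verified against central finite differences in
# the test suite.

#' Attention configuration
#'
#' @param hiddenUnits width d of the attention scoring network's hidden
#'   layer (default 140, the width at which held-out accuracy peaks).
#' @param fusionDim width of the fused representation in `weighted_sum`
#'   mode (default 128).
#' @param fusionMode `"weighted_sum"` (attention-weighted layers projected
#'   to `fusionDim` and summed; default) or `"weighted_concat"`
#'   (attention-weighted layers concatenated).
#' @return an `attentionConfig` list.
#' @export
attentionConfig <- function(hiddenUnits = 140, fusionDim = 128,
                            fusionMode = c("weighted_sum",
                                           "weighted_concat")) {
  fusionMode <- match.arg(fusionMode)
  stopifnot(hiddenUnits >= 1, fusionDim >= 1)
  structure(list(hiddenUnits = as.integer(hiddenUnits),
                 fusionDim = as.integer(fusionDim), fusionMode = fusionMode),
            class = "attentionConfig")
}

#' Stacked-GCN configuration
#'
#' @param nLayers number of graph-convolution blocks (default 5).
#' @param hidden width of each block's hidden and output maps (default 64).
#' @param dropout dropout rate applied to each block's input during
#'   training (default 0.2).
#' @param headHidden width of the relu hidden layer in the classifier head
#'   (default 32).
#' @param blockActivation `"sigmoid"` (default; each block ends in a
#'   sigmoid) or `"relu"`, provided for comparison.
#' @return an `sgcnConfig` list.
#' @export
sgcnConfig <- function(nLayers = 5, hidden = 64, dropout = 0.2,
                       headHidden = 32,
                       blockActivation = c("sigmoid", "relu")) {
  blockActivation <- match.arg(blockActivation)
  stopifnot(nLayers >= 1, hidden >= 1, dropout >= 0, dropout < 1)
  structure(list(nLayers = as.integer(nLayers), hidden = as.integer(hidden),
                 dropout = dropout, headHidden = as.integer(headHidden),
                 blockActivation = blockActivation), class = "sgcnConfig")
}

softmaxVec <- function(e) {
  z <- exp(e - max(e))
  z / sum(z)
}

softmaxRows <- function(L) {
  mx <- if (ncol(L) == 2L) pmax(L[, 1L], L[, 2L]) else apply(L, 1L, max)
  E <- exp(L - mx)
  E / rowSums(E)
}

xavier <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# Initialise all parameters for a variant. dims: per-omics feature counts.
# Draws from the current RNG state (seed before calling for determinism).
nnInit <- function(dims, acfg, scfg, useAttention, useSgcn,
                   fusionMode = acfg$fusionMode) {
  K <- length(dims)
  params <- list()
  if (useAttention) {
    d <- acfg$hiddenUnits
    params$attention <- lapply(dims, function(dk)
      list(W1 = xavier(d, dk), b = numeric(d), W2 = xavier(dk, d)))
    if (fusionMode == "weighted_sum")
      params$proj <- lapply(dims, function(dk) xavier(dk, acfg$fusionDim))
  }
  zWidth <- if (useAttention && fusionMode == "weighted_sum")
    acfg$fusionDim else sum(dims)
  if (useSgcn) {
    widths <- c(zWidth, rep(scfg$hidden, scfg$nLayers))
    # gain-corrected init for sigmoid blocks: the sigmoid attenuates signal
    # by ~4 (slope 1/4 at 0) and emits low-variance (0,1) values, so plain
    # Xavier collapses the forward signal by depth 5; W2 compensates the
    # sigmoid slope, W1 the reduced input variance
    g1 <- if (scfg$blockActivation == "sigmoid") 2 else 1
    g2 <- if (scfg$blockActivation == "sigmoid") 4 else 1
    params$sgcn <- lapply(seq_len(scfg$nLayers), function(l)
      list(W1 = g1 * xavier(widths[l], scfg$hidden),
           W2 = g2 * xavier(scfg$hidden, widths[l + 1L])))
    headIn <- scfg$hidden
  } else headIn <- zWidth
  params$head <- list(Wh = xavier(headIn, scfg$headHidden),
                      bh = numeric(scfg$headHidden),
                      Wo = xavier(scfg$headHidden, 2L), bo = numeric(2L))
  params
}

#' Per-omics attention weights
#'
#' Computes the feature attention vector for one omics layer: the layer
#' summary \eqn{h} is the column mean of the standardised feature matrix;
#' scores are \eqn{e = W_2 \tanh(W_1 h + b)} and the weights are
#' \eqn{\alpha = \mathrm{softmax}(e)}, non-negative and summing to 1.
#'
#' @param z numeric matrix (samples x features) or [OmicsMatrix-class].
#' @param W1 d x d_k scoring weight matrix.
#' @param b length-d bias vector.
#' @param W2 d_k x d scoring head matrix.
#' @return numeric vector of length d_k summing to 1.
#' @export
attentionWeights <- function(z, W1, b, W2) {
  if (is(z, "OmicsMatrix")) z <- assayValues(z)
  h <- colMeans(z)
  softmaxVec(as.numeric(W2 %*% tanh(as.numeric(W1 %*% h) + b)))
}

attnForwardOne <- function(Z, p) {
  h <- colMeans(Z)
  apre <- as.numeric(p$W1 %*% h) + p$b
  tv <- tanh(apre)
  e <- as.numeric(p$W2 %*% tv)
  alpha <- softmaxVec(e)
  # columns scaled by d_k * alpha (mean weight 1): uniform attention is then
  # the identity, so the weighted layer keeps the standardised feature scale
  # regardless of layer width
  list(h = h, tv = tv, alpha = alpha,
       Zt = sweep(Z, 2L, length(alpha) * alpha, "*"))
}

#' Attention-weighted fusion of omics layers
#'
#' Scales each layer's columns by its attention weights (normalised so the
#' mean column weight is 1, i.e. column j is multiplied by
#' \eqn{d_k \alpha_j}; uniform attention leaves the layer unchanged) and
#' fuses:
#' in `weighted_sum` mode each weighted layer is projected to a common
#' width and the projections are summed; in `weighted_concat` mode the
#' weighted layers are concatenated.
#'
#' @param matrices list of sample-aligned [OmicsMatrix-class] objects.
#' @param params parameter list as produced during training: per-omics
#'   `attention` entries (`W1`, `b`, `W2`) and, for `weighted_sum`,
#'   per-omics `proj` matrices.
#' @param fusionMode `"weighted_sum"` or `"weighted_concat"`.
#' @return list with `values` (fused n x d matrix), `attention` (list of
#'   per-omics weight vectors) and `sampleIds`.
#' @export
fuseFeatures <- function(matrices, params,
                         fusionMode = c("weighted_sum", "weighted_concat")) {
  fusionMode <- match.arg(fusionMode)
  ids <- sampleIds(matrices[[1L]])
  for (m in matrices)
    if (!identical(sampleIds(m), ids)) stop("sample misalignment across omics")
  caches <- lapply(seq_along(matrices), function(k)
    attnForwardOne(assayValues(matrices[[k]]), params$attention[[k]]))
  if (fusionMode == "weighted_sum") {
    Zf <- Reduce(`+`, lapply(seq_along(caches), function(k)
      caches[[k]]$Zt %*% params$proj[[k]]))
  } else {
    Zf <- do.call(cbind, lapply(caches, `[[`, "Zt"))
  }
  rownames(Zf) <- ids
  list(values = Zf, attention = lapply(caches, `[[`, "alpha"),
       sampleIds = ids)
}

#' Stacked graph-convolution forward pass
#'
#' Applies L blocks \eqn{Z^{(l+1)} = \sigma(\tanh(\hat A Z^{(l)} W_1^{(l)})
#' W_2^{(l)})} with \eqn{Z^{(0)}} the fused features; the convolution
#' operator \eqn{\hat A} enters exactly once per block. Each block ends in
#' a sigmoid, so outputs lie in (0, 1).
#'
#' @param z0 n x d numeric matrix of fused features (or the `values` entry
#'   of [fuseFeatures()] output).
#' @param g a [NormalizedGraph-class] with matching sample order, or a plain
#'   n x n operator matrix (use the identity for the graph-free ablation).
#' @param layers list of per-layer lists with matrices `W1`, `W2`.
#' @param blockActivation `"sigmoid"` or `"relu"` for the block output.
#' @return n x width matrix, the final block's output.
#' @export
sgcnForward <- function(z0, g, layers, blockActivation = "sigmoid") {
  Ahat <- if (is(g, "NormalizedGraph")) convMatrix(g) else g
  Z <- z0
  for (l in seq_along(layers)) {
    p <- layers[[l]]
    if (ncol(Z) != nrow(p$W1))
      stop("shape mismatch at graph-convolution layer ", l, ": input width ",
           ncol(Z), " vs W1 rows ", nrow(p$W1))
    Bm <- (Ahat %*% Z) %*% p$W1
    Cm <- tanh(Bm) %*% p$W2
    Z <- if (blockActivation == "sigmoid") 1 / (1 + exp(-Cm)) else pmax(Cm, 0)
  }
  Z
}

#' Classifier head
#'
#' One relu hidden layer followed by a linear softmax layer:
#' \eqn{H = \mathrm{relu}(Z^h W_h + b_h)}, class probabilities
#' \eqn{\mathrm{softmax}(H W_o + b_o)}.
#'
#' @param zh n x width matrix of high-level features.
#' @param head list with `Wh`, `bh`, `Wo`, `bo`.
#' @return data.frame with columns `sample_id` (row names of `zh`, or the
#'   row index), `probHighRisk` and `label` (1 if prob >= 0.5).
#' @export
classifyHead <- function(zh, head) {
  Hpre <- sweep(zh %*% head$Wh, 2L, head$bh, "+")
  H <- pmax(Hpre, 0)
  P <- softmaxRows(sweep(H %*% head$Wo, 2L, head$bo, "+"))
  ids <- rownames(zh)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(zh)))
  p <- P[, 2L]
  data.frame(sample_id = ids, probHighRisk = p,
             label = as.integer(p >= 0.5), row.names = NULL)
}

#' Binary cross-entropy loss
#'
#' \eqn{-(1/n)\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]}, with
#' probabilities clipped to \eqn{[\epsilon, 1-\epsilon]},
#' \eqn{\epsilon = 10^{-12}}.
#'
#' @param p numeric vector of predicted high-risk probabilities, or a
#'   prediction data.frame from [classifyHead()].
#' @param labels 0/1 vector aligned with `p` (matched by name/sample_id
#'   when both carry identifiers).
#' @return non-negative scalar loss.
#' @export
crossEntropy <- function(p, labels) {
  if (is.data.frame(p)) {
    ids <- p$sample_id
    p <- p$probHighRisk
    if (!is.null(names(labels))) labels <- labels[ids]
  }
  if (length(p) == 0L) stop("empty label set")
  stopifnot(length(p) == length(labels))
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- full forward/backward over a variant ---------------------------------

# Zs: list of feature matrices; Ahat: operator matrix or NULL (identity);
# dropMasks: NULL or list of matrices (inverted-dropout masks, one per
# sgcn block input). Returns probabilities plus every intermediate needed
# by nnBackward.
nnForward <- function(Zs, Ahat, params, opts, dropMasks = NULL) {
  cache <- list(Zs = Zs, dropMasks = dropMasks)
  if (opts$useAttention) {
    cache$attn <- lapply(seq_along(Zs), function(k)
      attnForwardOne(Zs[[k]], params$attention[[k]]))
    if (opts$fusionMode == "weighted_sum") {
      cache$Fk <- lapply(seq_along(Zs), function(k)
        cache$attn[[k]]$Zt %*% params$proj[[k]])
      Zf <- Reduce(`+`, cache$Fk)
    } else {
      Zf <- do.call(cbind, lapply(cache$attn, `[[`, "Zt"))
    }
  } else {
    Zf <- do.call(cbind, Zs)
  }
  cache$Zf <- Zf
  Z <- Zf
  if (opts$useSgcn) {
    cache$blocks <- vector("list", length(params$sgcn))
    for (l in seq_along(params$sgcn)) {
      p <- params$sgcn[[l]]
      Zin <- Z
      if (!is.null(dropMasks)) Zin <- Zin * dropMasks[[l]]
      AZ <- if (is.null(Ahat)) Zin else Ahat %*% Zin
      Bm <- AZ %*% p$W1
      Tm <- tanh(Bm)
      Cm <- Tm %*% p$W2
      Zout <- if (opts$blockActivation == "sigmoid")
        1 / (1 + exp(-Cm)) else pmax(Cm, 0)
      cache$blocks[[l]] <- list(Zin = Zin, AZ = AZ, Tm = Tm, Cm = Cm,
                                Zout = Zout)
      Z <- Zout
    }
  }
  cache$Zh <- Z
  h <- params$head
  cache$Hpre <- sweep(Z %*% h$Wh, 2L, h$bh, "+")
  cache$H <- pmax(cache$Hpre, 0)
  cache$P <- softmaxRows(sweep(cache$H %*% h$Wo, 2L, h$bo, "+"))
  cache
}

# Masked cross-entropy + L2 penalty on weight matrices (biases excluded).
nnLoss <- function(cache, params, y, maskIdx, weightDecay) {
  eps <- 1e-12
  p1 <- pmin(pmax(cache$P[maskIdx, 2L], eps), 1 - eps)
  yb <- y[maskIdx]
  ce <- -mean(yb * log(p1) + (1 - yb) * log(1 - p1))
  ce + weightDecay * sum(vapply(weightMats(params),
                                function(w) sum(w^2), numeric(1L)))
}

weightMats <- function(params) {
  out <- list()
  for (a in params$attention) out <- c(out, list(a$W1, a$W2))
  for (p in params$proj) out <- c(out, list(p))
  for (s in params$sgcn) out <- c(out, list(s$W1, s$W2))
  c(out, list(params$head$Wh, params$head$Wo))
}

nnBackward <- function(cache, params, opts, y, maskIdx, weightDecay,
                       Ahat = NULL) {
  n <- nrow(cache$P)
  nb <- length(maskIdx)
  Y <- matrix(0, n, 2L)
  Y[cbind(maskIdx, y[maskIdx] + 1L)] <- 1
  dlogits <- matrix(0, n, 2L)
  dlogits[maskIdx, ] <- (cache$P[maskIdx, , drop = FALSE] -
                           Y[maskIdx, , drop = FALSE]) / nb
  g <- list()
  h <- params$head
  gWo <- crossprod(cache$H, dlogits)
  gbo <- colSums(dlogits)
  dH <- tcrossprod(dlogits, h$Wo)
  dHpre <- dH * (cache$Hpre > 0)
  # field order must match the parameter skeleton (flatten alignment)
  g$head <- list(Wh = crossprod(cache$Zh, dHpre), bh = colSums(dHpre),
                 Wo = gWo, bo = gbo)
  dZ <- tcrossprod(dHpre, h$Wh)

  if (opts$useSgcn) {
    g$sgcn <- vector("list", length(params$sgcn))
    for (l in rev(seq_along(params$sgcn))) {
      p <- params$sgcn[[l]]
      bl <- cache$blocks[[l]]
      dC <- if (opts$blockActivation == "sigmoid")
        dZ * bl$Zout * (1 - bl$Zout) else dZ * (bl$Cm > 0)
      gW2 <- crossprod(bl$Tm, dC)
      dT <- tcrossprod(dC, p$W2)
      dB <- dT * (1 - bl$Tm^2)
      gW1 <- crossprod(bl$AZ, dB)
      dAZ <- tcrossprod(dB, p$W1)
      dZin <- if (is.null(Ahat)) dAZ else Ahat %*% dAZ  # Ahat symmetric
      if (!is.null(cache$dropMasks)) dZin <- dZin * cache$dropMasks[[l]]
      g$sgcn[[l]] <- list(W1 = gW1, W2 = gW2)
      dZ <- dZin
    }
  }
  dZf <- dZ

  if (opts$useAttention) {
    K <- length(cache$Zs)
    g$attention <- vector("list", K)
    if (opts$fusionMode == "weighted_sum") g$proj <- vector("list", K)
    off <- 0L
    for (k in seq_len(K)) {
      at <- cache$attn[[k]]
      Zk <- cache$Zs[[k]]
      dk <- ncol(Zk)
      if (opts$fusionMode == "weighted_sum") {
        g$proj[[k]] <- crossprod(at$Zt, dZf)
        dZt <- tcrossprod(dZf, params$proj[[k]])
      } else {
        dZt <- dZf[, off + seq_len(dk), drop = FALSE]
        off <- off + dk
      }
      dalpha <- dk * colSums(dZt * Zk)
      de <- at$alpha * (dalpha - sum(dalpha * at$alpha))
      pA <- params$attention[[k]]
      gW2 <- de %*% t(at$tv)
      dt <- as.numeric(t(pA$W2) %*% de)
      dapre <- dt * (1 - at$tv^2)
      g$attention[[k]] <- list(W1 = dapre %*% t(at$h), b = dapre, W2 = gW2)
    }
  }

  # same block order as params so flattened vectors align
  g <- g[names(params)]
  addDecay(g, params, weightDecay)
}

# L2 penalty gradient 2*wd*W on weight matrices only
addDecay <- function(g, params, wd) {
  if (wd == 0) return(g)
  for (k in seq_along(params$attention)) {
    g$attention[[k]]$W1 <- g$attention[[k]]$W1 + 2 * wd * params$attention[[k]]$W1
    g$attention[[k]]$W2 <- g$attention[[k]]$W2 + 2 * wd * params$attention[[k]]$W2
  }
  for (k in seq_along(params$proj))
    g$proj[[k]] <- g$proj[[k]] + 2 * wd * params$proj[[k]]
  for (l in seq_along(params$sgcn)) {
    g$sgcn[[l]]$W1 <- g$sgcn[[l]]$W1 + 2 * wd * params$sgcn[[l]]$W1
    g$sgcn[[l]]$W2 <- g$sgcn[[l]]$W2 + 2 * wd * params$sgcn[[l]]$W2
  }
  g$head$Wh <- g$head$Wh + 2 * wd * params$head$Wh
  g$head$Wo <- g$head$Wo + 2 * wd * params$head$Wo
  g
}

# flatten/unflatten a nested list of numeric arrays (stable order)
flattenParams <- function(p) {
  unlist(p, use.names = FALSE)
}

unflattenParams <- function(vec, skeleton) {
  utils::relist(vec, skeleton)
}

# one Adam step over nested parameter/gradient/moment trees (kept nested:
# relisting a flat vector every step costs more than the pass itself).
# Bias corrections are folded into the step size: with s2 = sqrt(1-b2^t),
# lr * mhat / (sqrt(vhat) + eps) == (lr * s2 / (1-b1^t)) * m / (sqrt(v) +
# eps * s2), exactly, saving two temporaries per leaf.
adamUpdate <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  s2 <- sqrt(1 - b2^t)
  adamRec(p, g, m, v, lr * s2 / (1 - b1^t), eps * s2, b1, b2)
}

adamRec <- function(p, g, m, v, lr2, eps2, b1, b2) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adamRec(p[[i]], g[[i]], m[[i]], v[[i]], lr2, eps2, b1, b2)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  p <- p - lr2 * m / (sqrt(v) + eps2)
  list(p = p, m = m, v = v)
}

nestedZero <- function(p) {
  if (is.list(p)) lapply(p, nestedZero) else p * 0
}
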