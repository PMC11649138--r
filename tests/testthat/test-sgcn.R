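test_that("graph-convolution blocks reduce to closed forms", {
  # zero weights: every block output is sigmoid(0) = 0.5
  z0 <- matrix(rnorm(12), 4, 3)
  Ahat <- diag(4)
  layers <- list(list(W1 = matrix(0, 3, 2), W2 = matrix(0, 2, 2)),
                 list(W1 = matrix(0, 2, 2), W2 = matrix(0, 2, 2)))
  out <- sgcnForward(z0, Ahat, layers)
  expect_equal(unname(out), matrix(0.5, 4, 2), tolerance = 1e-15)

  # identity operator, one layer: plain two-map feedforward block
  set.seed(3)
  W1 <- matrix(rnorm(6), 3, 2); W2 <- matrix(rnorm(4), 2, 2)
  out1 <- sgcnForward(z0, diag(4), list(list(W1 = W1, W2 = W2)))
  oracle <- 1 / (1 + exp(-(tanh(z0 %*% W1) %*% W2)))
  expect_equal(out1, oracle, tolerance = 1e-12)

  # 2-node averaging operator with opposite scalar features cancels
  Ahat2 <- matrix(0.5, 2, 2)
  out2 <- sgcnForward(matrix(c(1, -1), 2, 1), Ahat2,
                      list(list(W1 = matrix(1), W2 = matrix(1))))
  expect_equal(unname(out2), matrix(0.5, 2, 1), tolerance = 1e-15)

  expect_error(sgcnForward(z0, diag(4),
                           list(list(W1 = matrix(0, 5, 2),
                                     W2 = matrix(0, 2, 2)))),
               "layer 1")
})

test_that("classifier head computes relu-softmax probabilities", {
  zh <- matrix(rnorm(8), 4, 2, dimnames = list(sprintf("S%d", 1:4), NULL))
  headZero <- list(Wh = matrix(0, 2, 3), bh = numeric(3),
                   Wo = matrix(0, 3, 2), bo = numeric(2))
  pred <- classifyHead(zh, headZero)
  expect_equal(pred$probHighRisk, rep(0.5, 4))
  expect_equal(pred$label, rep(1L, 4))  # 0.5 >= 0.5 threshold

  # logits (0, ln 3) -> p(class 1) = 0.75
  headLogit <- list(Wh = matrix(0, 2, 1), bh = 1,
                    Wo = matrix(c(0, log(3)), 1, 2), bo = c(0, 0))
  pred2 <- classifyHead(zh, headLogit)
  expect_equal(pred2$probHighRisk, rep(0.75, 4), tolerance = 1e-12)

  # softmax rows always sum to 1
  set.seed(10)
  headR <- list(Wh = matrix(rnorm(6), 2, 3), bh = rnorm(3),
                Wo = matrix(rnorm(6), 3, 2), bo = rnorm(2))
  ns <- asNamespace("omicsSGCN")
  H <- pmax(sweep(zh %*% headR$Wh, 2, headR$bh, "+"), 0)
  P <- ns$softmaxRows(sweep(H %*% headR$Wo, 2, headR$bo, "+"))
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
})

test_that("cross-entropy matches hand values and handles edge cases", {
  expect_lt(crossEntropy(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(crossEntropy(rep(0.5, 6), rep(c(0, 1), 3)), log(2),
               tolerance = 1e-12)
  expect_equal(crossEntropy(c(0.9, 0.2), c(1, 0)),
               -0.5 * (log(0.9) + log(0.8)), tolerance = 1e-12)
  expect_error(crossEntropy(numeric(0), numeric(0)), "empty")
})

test_that("analytic gradients match finite differences through the stack", {
  ns <- asNamespace("omicsSGCN")
  set.seed(42)
  n <- 6; dims <- c(4, 3)
  Zs <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
  A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
  Ahat <- convMatrix(normalizeAdjacency(new("SampleGraph",
    sampleIds = as.character(1:n), adjacency = A / max(A))))
  acfg <- attentionConfig(hiddenUnits = 7, fusionDim = 5)
  scfg <- sgcnConfig(nLayers = 5, hidden = 4, dropout = 0, headHidden = 3)
  y <- c(1, 0, 1, 0, 1, 0); mask <- 1:6; wd <- 0.001

  cases <- list(
    list(useAttention = TRUE, useSgcn = TRUE, fusionMode = "weighted_sum"),
    list(useAttention = TRUE, useSgcn = FALSE, fusionMode = "weighted_concat"))
  for (opts in cases) {
    opts$blockActivation <- "sigmoid"
    params <- ns$nnInit(dims, acfg, scfg, opts$useAttention, opts$useSgcn,
                        opts$fusionMode)
    Ah <- if (opts$useSgcn) Ahat else NULL
    theta <- ns$flattenParams(params)
    lossAt <- function(th) {
      p <- ns$unflattenParams(th, params)
      ns$nnLoss(ns$nnForward(Zs, Ah, p, opts), p, y, mask, wd)
    }
    cache <- ns$nnForward(Zs, Ah, params, opts)
    ga <- ns$flattenParams(ns$nnBackward(cache, params, opts, y, mask, wd, Ah))
    set.seed(1)
    idx <- sort(sample(length(theta), min(150, length(theta))))
    h <- 1e-3  # 4th-order central differences
    gn <- vapply(idx, function(i) {
      f <- function(d) { tp <- theta; tp[i] <- tp[i] + d; lossAt(tp) }
      (8 * (f(h) - f(-h)) - (f(2 * h) - f(-2 * h))) / (12 * h)
    }, numeric(1))
    rel <- abs(ga[idx] - gn) / pmax(abs(ga[idx]) + abs(gn), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("identity-graph model matches an independent feedforward oracle", {
  ns <- asNamespace("omicsSGCN")
  set.seed(15)
  n <- 5
  Z <- matrix(rnorm(n * 4), n, 4)
  scfg <- sgcnConfig(nLayers = 3, hidden = 3, dropout = 0, headHidden = 2)
  params <- ns$nnInit(4, attentionConfig(), scfg, FALSE, TRUE)
  opts <- list(useAttention = FALSE, useSgcn = TRUE,
               fusionMode = "weighted_sum", blockActivation = "sigmoid")
  cache <- ns$nnForward(list(Z), NULL, params, opts)

  # independently coded feedforward stack with shared weights
  X <- Z
  for (l in 1:3)
    X <- 1 / (1 + exp(-(tanh(X %*% params$sgcn[[l]]$W1) %*%
                          params$sgcn[[l]]$W2)))
  H <- pmax(sweep(X %*% params$head$Wh, 2, params$head$bh, "+"), 0)
  P <- exp(sweep(H %*% params$head$Wo, 2, params$head$bo, "+"))
  P <- P / rowSums(P)
  expect_lt(max(abs(cache$P - P)), 1e-10)
  expect_lt(max(abs(cache$Zh - X)), 1e-10)
})
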