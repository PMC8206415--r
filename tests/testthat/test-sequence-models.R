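test_that("encoding dimensions follow the GRU configuration", {
  m <- buildRCN(rcnConfig(variant = "full_seq", featureDim = 256L, seed = 1))
  f <- random_features(10, d = 256, seed = 1)
  enc <- encodeSequence(m, f)
  expect_equal(dim(enc$h), c(10L, 128L))        # 64 per direction
  m1 <- buildRCN(rcnConfig(variant = "full_seq", featureDim = 256L,
                           bidirectional = FALSE, seed = 1))
  expect_equal(dim(encodeSequence(m1, f)$h), c(10L, 64L))
  # deterministic in evaluation mode
  expect_identical(enc$h, encodeSequence(m, f)$h)
  expect_error(encodeSequence(m, random_features(10, d = 5)), "dimension")
})

test_that("the convex kernel is a normalized exponential of the raw weights", {
  expect_equal(toeplitzKernel(c(0, 0, 0)), rep(1 / 3, 3))
  raw <- c(1, 2, 3)
  expect_equal(toeplitzKernel(raw), exp(raw) / sum(exp(raw)),
               tolerance = 1e-12)
  expect_equal(toeplitzKernel(c(1000, 0, 0)), c(1, 0, 0))  # limit case
  set.seed(1)
  for (D in 0:5) {
    k <- toeplitzKernel(rnorm(2 * D + 1))
    expect_true(all(k >= 0))
    expect_equal(sum(k), 1)
  }
  expect_error(toeplitzKernel(c(1, 2)), "odd")
})

test_that("Toeplitz attention maps have the banded, renormalized structure", {
  # D = 0 reduces to the identity for any N
  for (N in c(1, 5, 17)) {
    expect_equal(toeplitzAttentionMap(1, N), diag(N))
  }
  # hand-renormalized oracle at the edges
  A <- toeplitzAttentionMap(c(0.25, 0.5, 0.25), 4)
  expect_equal(A[1, ], c(2 / 3, 1 / 3, 0, 0))
  expect_equal(A[2, ], c(0.25, 0.5, 0.25, 0))
  expect_equal(A[3, ], c(0, 0.25, 0.5, 0.25))
  expect_equal(A[4, ], c(0, 0, 1 / 3, 2 / 3))
  set.seed(3)
  for (r in 1:20) {
    D <- sample(0:5, 1); N <- sample(1:20, 1)
    A <- toeplitzAttentionMap(toeplitzKernel(rnorm(2 * D + 1)), N)
    expect_equal(rowSums(A), rep(1, N))
    expect_true(all(A >= 0))
    expect_true(all(A[abs(row(A) - col(A)) > D] == 0))
  }
  # masked columns lose their weight, rows renormalize over survivors
  k <- c(0.25, 0.5, 0.25)
  Am <- toeplitzAttentionMap(k, 4, mask = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(Am[, 4], rep(0, 4))
  expect_equal(rowSums(Am[1:3, ]), rep(1, 3))
  expect_equal(Am[3, ], c(0, 1 / 3, 2 / 3, 0))
})

test_that("attention application is the row-weighted sum of encodings", {
  set.seed(5)
  h <- matrix(rnorm(6 * 4), 6, 4)
  expect_identical(applyAttention(diag(6), h), h)
  hconst <- matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4)
  A <- matrix(stats::rexp(36), 6, 6); A <- A / rowSums(A)
  expect_equal(applyAttention(A, hconst), hconst)   # convexity
  # brute-force double-loop oracle
  want <- matrix(0, 6, 4)
  for (n in 1:6) for (m in 1:6) want[n, ] <- want[n, ] + A[n, m] * h[m, ]
  expect_lt(max(abs(applyAttention(A, h) - want)), 1e-10)
  expect_error(applyAttention(A[1:5, ], h), "match")
})

test_that("global attention rows are masked probability vectors", {
  set.seed(6)
  params <- list(W1 = matrix(rnorm(12), 3, 4), W2 = matrix(rnorm(12), 3, 4),
                 v = rnorm(3))
  h <- matrix(rnorm(5 * 4), 5, 4)
  A <- globalAttentionScores(h, params)
  expect_equal(rowSums(A), rep(1, 5))
  expect_true(all(A >= 0))
  expect_equal(globalAttentionScores(h[1, , drop = FALSE], params),
               matrix(1, 1, 1))
  maskA <- globalAttentionScores(h, params, mask = c(TRUE, TRUE, FALSE,
                                                     TRUE, FALSE))
  expect_equal(maskA[, 3], rep(0, 5))
  expect_equal(maskA[, 5], rep(0, 5))
  expect_equal(rowSums(maskA), rep(1, 5))
  # zero scoring vector gives uniform attention over unmasked slices
  params$v <- params$v * 0
  expect_equal(globalAttentionScores(h, params),
               matrix(1 / 5, 5, 5))
})

test_that("decoders emit probability rows and handle length-1 sequences", {
  for (variant in c("full_seq", "toeplitz", "global_attention",
                    "partial_seq")) {
    m <- buildRCN(tiny_rcn_config(variant))
    f <- random_features(7, d = 6, seed = 3)
    res <- predictRCN(m, f)
    expect_equal(rowSums(res$probs), rep(1, 7), tolerance = 1e-6)
    expect_true(all(res$labels %in% 0:2))
    res1 <- predictRCN(m, random_features(1, d = 6, seed = 4))
    expect_equal(rowSums(res1$probs), 1, tolerance = 1e-6)
  }
})

test_that("Toeplitz D=0 with shared weights equals the full-sequence model", {
  toep <- buildRCN(tiny_rcn_config("toeplitz", D = 0L))
  full <- buildRCN(tiny_rcn_config("full_seq"))
  full@params$enc_f <- toep@params$enc_f
  full@params$enc_b <- toep@params$enc_b
  full@params$dec <- toep@params$dec
  for (r in 1:20) {
    f <- random_features(sample(2:15, 1), d = 6, seed = 100 + r)
    pt <- predictRCN(toep, f)$probs
    pf <- predictRCN(full, f)$probs
    expect_lt(max(abs(pt - pf)), 1e-5)
  }
})

test_that("padded slices never change unmasked predictions", {
  for (variant in c("toeplitz", "full_seq", "global_attention")) {
    m <- buildRCN(tiny_rcn_config(variant))
    f <- random_features(8, d = 6, seed = 21)
    base <- predictRCN(m, f)
    padded <- rbind(f@features, matrix(0, 4, 6))
    res <- predictRCN(m, padded, mask = c(rep(TRUE, 8), rep(FALSE, 4)))
    expect_lt(max(abs(res$probs[1:8, ] - base$probs)), 1e-6)
    enc <- encodeSequence(m, padded, mask = c(rep(TRUE, 8), rep(FALSE, 4)))
    expect_true(all(enc$h[9:12, ] == 0))
  }
})

test_that("full-sequence predictions use slice order", {
  m <- buildRCN(tiny_rcn_config("full_seq"))
  f <- random_features(9, d = 6, seed = 31)
  fwdp <- predictRCN(m, f)$probs
  revp <- predictRCN(m, f@features[9:1, ])$probs
  expect_gt(max(abs(fwdp - revp[9:1, ])), 1e-4)
})

test_that("partial-sequence windows replicate terminal slices", {
  f <- random_features(5, d = 6, seed = 41)
  y <- c(0L, 0L, 1L, 2L, 2L)
  pairs <- makePartialSequences(f, y, neighborhood = 3L)
  expect_length(pairs, 5L)
  expect_equal(pairs[[1]]$window,
               f@features[c(1, 1, 2), ], ignore_attr = TRUE)
  expect_equal(pairs[[5]]$window,
               f@features[c(4, 5, 5), ], ignore_attr = TRUE)
  expect_equal(vapply(pairs, `[[`, integer(1), "label"), y)
  # N = 1 degenerates to single-slice training
  p1 <- makePartialSequences(f, y, neighborhood = 1L)
  expect_equal(p1[[3]]$window, f@features[3, , drop = FALSE],
               ignore_attr = TRUE)
  for (r in 1:10) {
    n <- sample(2:30, 1)
    expect_length(makePartialSequences(random_features(n, 4, r),
                                       sample(0:2, n, TRUE)), n)
  }
})

test_that("sequence-model analytic gradients match central differences", {
  ns <- asNamespace("rcmstrata")
  for (variant in c("toeplitz", "global_attention")) {
    cfg <- unclass(tiny_rcn_config(variant))
    params <- ns$.with_seed(7, ns$.rcn_init_params(cfg))
    set.seed(42)
    X <- matrix(rnorm(6 * 5), 6, 5)
    y <- c(0L, 1L, 1L, 2L, 2L)
    loss <- function(p) ns$.ce_loss(ns$.rcn_forward(p, cfg, X)$probs, y)
    fwd <- ns$.rcn_forward(params, cfg, X, train = TRUE, y = y)
    g <- ns$.rcn_backward(params, cfg, X, fwd, y)
    ng <- numeric_gradient(loss, params)
    expect_lt(max_param_diff(g, ng), 1e-5)
  }
})

test_that("training improves the model and honours lr and L1 settings", {
  ds <- toy_feature_dataset(16, seed = 2)
  tr <- 1:12; va <- 13:16
  cfg <- rcnConfig(variant = "toeplitz", D = 1L, gruHidden = 8L,
                   featureDim = 6L, epochs = 20L, recurrentDropout = 0.1,
                   l1Recurrent = 0.001, seed = 5)
  fit <- trainRCN(buildRCN(cfg), ds$features[tr], ds$labels[tr],
                  ds$features[va], ds$labels[va])
  h <- fit$history
  expect_equal(nrow(h), 20L)
  expect_false(is.unsorted(rev(cummin(h$val_loss))))  # best-so-far record
  expect_gt(max(h$val_accuracy), h$val_accuracy[1])
  expect_true(fit$model@trained)
  # reproducibility: identical history under an identical seed
  fit2 <- trainRCN(buildRCN(cfg), ds$features[tr], ds$labels[tr],
                   ds$features[va], ds$labels[va])
  expect_equal(h, fit2$history)
  # a strong L1 penalty shrinks the recurrent weights
  cfg_l1 <- rcnConfig(variant = "toeplitz", D = 1L, gruHidden = 8L,
                      featureDim = 6L, epochs = 10L, l1Recurrent = 10,
                      recurrentDropout = 0, seed = 5)
  cfg_l0 <- rcnConfig(variant = "toeplitz", D = 1L, gruHidden = 8L,
                      featureDim = 6L, epochs = 10L, l1Recurrent = 0,
                      recurrentDropout = 0, seed = 5)
  f1 <- trainRCN(buildRCN(cfg_l1), ds$features[tr], ds$labels[tr],
                 ds$features[va], ds$labels[va])
  f0 <- trainRCN(buildRCN(cfg_l0), ds$features[tr], ds$labels[tr],
                 ds$features[va], ds$labels[va])
  expect_lt(sum(abs(f1$model@params$enc_f$Wh)),
            sum(abs(f0$model@params$enc_f$Wh)))
  # zero learning rate leaves the parameters untouched
  cfg0 <- rcnConfig(variant = "toeplitz", D = 1L, gruHidden = 8L,
                    featureDim = 6L, epochs = 2L, lr = 0, seed = 5)
  m0 <- buildRCN(cfg0)
  fit0 <- trainRCN(m0, ds$features[tr], ds$labels[tr],
                   ds$features[va], ds$labels[va])
  expect_equal(max_param_diff(fit0$model@params, m0@params), 0)
  # a validation set is mandatory for snapshot selection
  expect_error(trainRCN(buildRCN(cfg), ds$features[tr], ds$labels[tr],
                        list(), list()),
               "validation")
})
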