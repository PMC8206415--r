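#' Configuration for recurrent sequence models over slice features
#'
#' Defaults follow the reference training recipe: 64 GRU units per direction
#' (one recurrent layer per direction), 200 epochs with batches of 4
#' sequences at learning rate 0.001, 10% dropout on the recurrent
#' connections, an L1 penalty with weight 0.05 on the recurrent weight
#' matrices, and a maximum sequence length of 71 slices.
#'
#' @param variant one of `"full_seq"` (identity attention), `"partial_seq"`
#'   (classify the middle slice of a short window), `"global_attention"`
#'   (additive attention over the whole stack, GRU decoder), `"toeplitz"`
#'   (learnable convex kernel of length `2D+1` applied at every depth,
#'   fully connected decoder).
#' @param D Toeplitz attention half-width (support `2D+1`); `D = 0` reduces
#'   the attention map to the identity and the model to the full-sequence
#'   variant.
#' @param neighborhood odd window length for `partial_seq` (default 3).
#' @param gruHidden GRU units per direction.
#' @param bidirectional use forward and backward GRUs (default TRUE).
#' @param recurrentDropout dropout rate on recurrent connections during
#'   training (variational: one mask per sequence).
#' @param l1Recurrent L1 penalty weight on recurrent weight matrices.
#' @param lr Adam learning rate.
#' @param batchStacks sequences per gradient step.
#' @param epochs training epochs.
#' @param maxLen maximum sequence length; longer stacks are clipped to their
#'   first `maxLen` slices.
#' @param featureDim dimension of the frozen slice features.
#' @param attnDim hidden width of the additive attention scorer
#'   (`global_attention` only).
#' @param decoderHidden GRU units of the decoder (`global_attention` only).
#' @param teacherForcing feed the true previous label (one-hot) instead of
#'   the model's own previous probabilities during training.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return A list of class `RCNConfig`.
#' @export
rcnConfig <- function(variant = c("toeplitz", "full_seq", "partial_seq",
                                  "global_attention"),
                      D = 1L, neighborhood = 3L, gruHidden = 64L,
                      bidirectional = TRUE, recurrentDropout = 0.10,
                      l1Recurrent = 0.05, lr = 1e-3, batchStacks = 4L,
                      epochs = 200L, maxLen = 71L, featureDim = 256L,
                      attnDim = 32L, decoderHidden = 64L,
                      teacherForcing = FALSE, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(D >= 0L, neighborhood %% 2L == 1L, gruHidden >= 1L,
            recurrentDropout >= 0, recurrentDropout <= 1,
            l1Recurrent >= 0, lr >= 0, batchStacks >= 1L, epochs >= 1L,
            maxLen >= 1L, featureDim >= 1L)
  structure(list(variant = variant, D = as.integer(D),
                 neighborhood = as.integer(neighborhood),
                 gru_hidden = as.integer(gruHidden),
                 bidirectional = isTRUE(bidirectional),
                 recurrent_dropout = recurrentDropout,
                 l1_recurrent = l1Recurrent, lr = lr,
                 batch_stacks = as.integer(batchStacks),
                 epochs = as.integer(epochs), max_len = as.integer(maxLen),
                 feature_dim = as.integer(featureDim),
                 attn_dim = as.integer(attnDim),
                 decoder_hidden = as.integer(decoderHidden),
                 teacher_forcing = isTRUE(teacherForcing),
                 seed = as.integer(seed)),
            class = "RCNConfig")
}

.enc_dim <- function(cfg) cfg$gru_hidden * (1L + cfg$bidirectional)

.gru_init <- function(d, h) {
  list(Wx = rbind(.glorot(h, d), .glorot(h, d), .glorot(h, d)),
       Wh = rbind(.glorot(h, h), .glorot(h, h), .glorot(h, h)),
       b = rep(0, 3 * h))
}

.rcn_init_params <- function(cfg) {
  d <- cfg$feature_dim; h <- cfg$gru_hidden; dh <- .enc_dim(cfg)
  p <- list(enc_f = .gru_init(d, h))
  if (cfg$bidirectional) p$enc_b <- .gru_init(d, h)
  p <- switch(cfg$variant,
    toeplitz = c(p, list(kernel_raw = rep(0, 2 * cfg$D + 1),
                         dec = list(W = .glorot(3L, dh + 3L), b = rep(0, 3)))),
    full_seq = c(p, list(dec = list(W = .glorot(3L, dh + 3L), b = rep(0, 3)))),
    partial_seq = c(p, list(dec = list(W = .glorot(3L, dh), b = rep(0, 3)))),
    global_attention = c(p, list(
      att = list(W1 = .glorot(cfg$attn_dim, dh), W2 = .glorot(cfg$attn_dim, dh),
                 v = stats::runif(cfg$attn_dim, -0.1, 0.1)),
      dec_gru = .gru_init(dh + 3L, cfg$decoder_hidden),
      dec = list(W = .glorot(3L, cfg$decoder_hidden), b = rep(0, 3)))))
  p
}

#' Build an untrained recurrent sequence model
#'
#' @param config an [rcnConfig()].
#' @return An [RCNModel] with seeded random initialization. The Toeplitz
#'   kernel starts uniform (zero raw weights).
#' @export
buildRCN <- function(config = rcnConfig()) {
  if (!inherits(config, "RCNConfig"))
    stop("config must be created by rcnConfig()")
  params <- .with_seed(config$seed, .rcn_init_params(config))
  new("RCNModel", config = unclass(config), params = params, trained = FALSE)
}

#' Convex attention kernel from unconstrained weights
#'
#' The Toeplitz attention kernel must have non-negative entries summing to
#' one (a convex combiner). It is realized as normalized exponentials of
#' free weights, which satisfies the constraint for any raw values and keeps
#' the parameterization differentiable for training.
#'
#' @param raw numeric vector of odd length `2D + 1`.
#' @return The convex kernel (same length, entries >= 0, summing to 1).
#' @export
#' @examples
#' toeplitzKernel(c(0, 0, 0))  # uniform 1/3
toeplitzKernel <- function(raw) {
  if (length(raw) %% 2L == 0L)
    stop("kernel length must be odd (2D + 1)")
  e <- exp(raw - max(raw))
  e / sum(e)
}

#' Build a Toeplitz attention map
#'
#' Interior row `n` carries the kernel on columns `n - D .. n + D`, so the
#' map has constant diagonals (a Toeplitz structure) and zero support outside
#' the band `|m - n| <= D`. Rows whose window is clipped by a sequence edge
#' or by the mask are renormalized over the surviving entries, preserving
#' the convex-combiner contract. With `D = 0` the map is the identity matrix
#' for any `N`, recovering the full-sequence model.
#'
#' @param kernel convex kernel of length `2D + 1` (see [toeplitzKernel()]).
#' @param N sequence length (rows/columns of the map).
#' @param mask optional logical vector of length `N`; `FALSE` columns (padded
#'   slices) get zero weight in every row.
#' @return An `N x N` row-stochastic matrix.
#' @export
toeplitzAttentionMap <- function(kernel, N, mask = NULL) {
  stopifnot(N >= 1L, length(kernel) %% 2L == 1L)
  D <- (length(kernel) - 1L) %/% 2L
  if (is.null(mask)) mask <- rep(TRUE, N)
  stopifnot(length(mask) == N)
  A <- matrix(0, N, N)
  for (n in seq_len(N)) {
    cols <- max(1L, n - D):min(N, n + D)
    cols <- cols[mask[cols]]
    if (length(cols) == 0L) { A[n, n] <- 1; next }
    k <- kernel[cols - n + D + 1L]
    A[n, cols] <- k / sum(k)
  }
  A
}

#' Additive (global) attention scores
#'
#' Scores every pair of encodings with a small learned network,
#' `score(n, m) = v . tanh(W1 h_n + W2 h_m)`, and normalizes each row over
#' the unmasked positions with normalized exponentials. Masked (padded)
#' columns receive zero weight in every row; there is no sparsity
#' constraint, so every real slice can attend to every other.
#'
#' @param h numeric matrix of encodings, slices x dimensions.
#' @param params list with `W1`, `W2` (attnDim x dim) and `v` (attnDim).
#' @param mask optional logical vector marking real slices.
#' @return An `N x N` row-stochastic attention map.
#' @export
globalAttentionScores <- function(h, params, mask = NULL) {
  H <- t(h)                              # dim x N
  N <- ncol(H)
  if (is.null(mask)) mask <- rep(TRUE, N)
  S1 <- params$W1 %*% H                  # da x N
  S2 <- params$W2 %*% H
  A <- matrix(0, N, N)
  for (n in seq_len(N)) {
    Tn <- tanh(S1[, n] + S2)             # da x N
    e <- as.vector(crossprod(params$v, Tn))
    e[!mask] <- -Inf
    e <- e - max(e[mask])
    w <- exp(e)
    A[n, ] <- w / sum(w[mask])
  }
  A
}

#' Apply an attention map to a sequence of encodings
#'
#' Each context vector is the attention-weighted sum of the encodings:
#' `context_n = sum_m A[n, m] h_m`. With an identity map the output equals
#' the input exactly; because rows are convex weights, each context vector
#' lies in the convex hull of the encodings in its window.
#'
#' @param A an `N x N` row-stochastic attention map.
#' @param h numeric matrix of encodings, slices x dimensions.
#' @return Numeric matrix of context vectors, slices x dimensions.
#' @export
applyAttention <- function(A, h) {
  if (nrow(A) != ncol(A) || nrow(A) != nrow(h))
    stop("attention map and encoding dimensions do not match")
  A %*% h
}

# ---- internal forward/backward ---------------------------------------------

.drop_mask <- function(h, rate, train) {
  if (!train || rate <= 0) rep(1, h)
  else stats::rbinom(h, 1L, 1 - rate) / (1 - rate)
}

# encoder over the true (unpadded) sequence: X is d x n
.encode_fwd <- function(params, cfg, X, dmf = NULL, dmb = NULL) {
  h <- cfg$gru_hidden
  if (is.null(dmf)) dmf <- rep(1, h)
  if (is.null(dmb)) dmb <- rep(1, h)
  ff <- cpp_gru_forward(X, params$enc_f$Wx, params$enc_f$Wh, params$enc_f$b,
                        rep(0, h), dmf)
  H <- ff$H
  fb <- NULL
  if (cfg$bidirectional) {
    Xr <- X[, ncol(X):1, drop = FALSE]
    fb <- cpp_gru_forward(Xr, params$enc_b$Wx, params$enc_b$Wh, params$enc_b$b,
                          rep(0, h), dmb)
    H <- rbind(H, fb$H[, ncol(X):1, drop = FALSE])
  }
  list(H = H, ff = ff, fb = fb, dmf = dmf, dmb = dmb)
}

.encode_bwd <- function(params, cfg, X, enc, dH) {
  h <- cfg$gru_hidden
  g <- list()
  bf <- cpp_gru_backward(X, params$enc_f$Wx, params$enc_f$Wh, rep(0, h),
                         enc$dmf, enc$ff, dH[seq_len(h), , drop = FALSE])
  g$enc_f <- list(Wx = bf$dWx, Wh = bf$dWh, b = as.vector(bf$db))
  if (cfg$bidirectional) {
    n <- ncol(X)
    Xr <- X[, n:1, drop = FALSE]
    dHb <- dH[h + seq_len(h), n:1, drop = FALSE]
    bb <- cpp_gru_backward(Xr, params$enc_b$Wx, params$enc_b$Wh, rep(0, h),
                           enc$dmb, enc$fb, dHb)
    g$enc_b <- list(Wx = bb$dWx, Wh = bb$dWh, b = as.vector(bb$db))
  }
  g
}

.onehot3 <- function(y) { m <- matrix(0, 3, length(y)); m[cbind(y + 1L, seq_along(y))] <- 1; m }

# fully connected autoregressive decoder (toeplitz / full_seq):
# p_n = softmax(W [ctx_n; p_{n-1}] + b), p_0 = 0
.decode_fc_fwd <- function(dec, Ctx, prev_forced = NULL) {
  n <- ncol(Ctx)
  probs <- matrix(0, 3, n)
  prev <- rep(0, 3)
  inputs <- matrix(0, nrow(Ctx) + 3L, n)
  for (t in seq_len(n)) {
    if (!is.null(prev_forced) && t > 1L) prev <- prev_forced[, t - 1L]
    inp <- c(Ctx[, t], prev)
    inputs[, t] <- inp
    p <- as.vector(.softmax_cols(matrix(dec$W %*% inp + dec$b, ncol = 1)))
    probs[, t] <- p
    prev <- p
  }
  list(probs = probs, inputs = inputs)
}

.decode_fc_bwd <- function(dec, cache, y, n_norm, autoregressive = TRUE) {
  probs <- cache$probs; inputs <- cache$inputs
  n <- ncol(probs); dh <- nrow(inputs) - 3L
  dW <- dec$W * 0; db <- rep(0, 3)
  dCtx <- matrix(0, dh, n)
  dp_carry <- rep(0, 3)
  for (t in rev(seq_len(n))) {
    p <- probs[, t]
    dlog <- p * (dp_carry - sum(p * dp_carry))      # via softmax jacobian
    if (!is.null(y)) { dlog <- dlog + (p - .onehot3(y[t])[, 1]) / n_norm }
    dW <- dW + dlog %*% t(inputs[, t])
    db <- db + dlog
    dinp <- as.vector(crossprod(dec$W, dlog))
    dCtx[, t] <- dinp[seq_len(dh)]
    dp_carry <- if (autoregressive) dinp[dh + 1:3] else rep(0, 3)
  }
  list(dW = dW, db = db, dCtx = dCtx)
}

# plain-R GRU cell (decoder use; small dimensions)
.gru_cell_fwd <- function(x, h, W, dm) {
  hd <- length(h)
  hpd <- dm * h
  pre <- W$Wx %*% x + W$Wh %*% hpd + W$b
  z <- 1 / (1 + exp(-pre[seq_len(hd)]))
  r <- 1 / (1 + exp(-pre[hd + seq_len(hd)]))
  rhd <- r * hpd
  cpre <- W$Wx[2 * hd + seq_len(hd), ] %*% x +
    W$Wh[2 * hd + seq_len(hd), ] %*% rhd + W$b[2 * hd + seq_len(hd)]
  c_ <- tanh(cpre)
  hn <- (1 - z) * h + z * c_
  list(h = as.vector(hn), x = x, hprev = h, hpd = hpd, z = as.vector(z),
       r = as.vector(r), c = as.vector(c_), rhd = as.vector(rhd))
}

.gru_cell_bwd <- function(cache, dh, W, dm, g) {
  hd <- length(cache$hprev)
  z <- cache$z; r <- cache$r; c_ <- cache$c
  dz <- dh * (c_ - cache$hprev)
  dc <- dh * z
  dhprev <- dh * (1 - z)
  dc_pre <- dc * (1 - c_^2)
  dz_pre <- dz * z * (1 - z)
  Whz <- W$Wh[seq_len(hd), , drop = FALSE]
  Whr <- W$Wh[hd + seq_len(hd), , drop = FALSE]
  Whc <- W$Wh[2 * hd + seq_len(hd), , drop = FALSE]
  drhd <- as.vector(crossprod(Whc, dc_pre))
  dr <- drhd * cache$hpd
  dhpd <- drhd * r
  dr_pre <- dr * r * (1 - r)
  dhpd <- dhpd + as.vector(crossprod(Whz, dz_pre)) +
    as.vector(crossprod(Whr, dr_pre))
  dpre <- c(dz_pre, dr_pre, dc_pre)
  g$Wx <- g$Wx + dpre %*% t(cache$x)
  g$Wh[seq_len(hd), ] <- g$Wh[seq_len(hd), ] + dz_pre %*% t(cache$hpd)
  g$Wh[hd + seq_len(hd), ] <- g$Wh[hd + seq_len(hd), ] + dr_pre %*% t(cache$hpd)
  g$Wh[2 * hd + seq_len(hd), ] <- g$Wh[2 * hd + seq_len(hd), ] +
    dc_pre %*% t(cache$rhd)
  g$b <- g$b + dpre
  dx <- as.vector(crossprod(W$Wx, dpre))
  list(dx = dx, dhprev = dhprev + dm * dhpd, g = g)
}

# GRU + FC autoregressive decoder (global attention)
.decode_gru_fwd <- function(params, cfg, Ctx, dm = NULL, prev_forced = NULL) {
  n <- ncol(Ctx); g <- cfg$decoder_hidden
  if (is.null(dm)) dm <- rep(1, g)
  s <- rep(0, g)
  prev <- rep(0, 3)
  probs <- matrix(0, 3, n)
  cells <- vector("list", n)
  states <- matrix(0, g, n)
  for (t in seq_len(n)) {
    if (!is.null(prev_forced) && t > 1L) prev <- prev_forced[, t - 1L]
    cell <- .gru_cell_fwd(c(Ctx[, t], prev), s, params$dec_gru, dm)
    s <- cell$h
    p <- as.vector(.softmax_cols(matrix(params$dec$W %*% s + params$dec$b,
                                        ncol = 1)))
    probs[, t] <- p
    cells[[t]] <- cell
    states[, t] <- s
    prev <- p
  }
  list(probs = probs, cells = cells, states = states, dm = dm)
}

.decode_gru_bwd <- function(params, cfg, cache, y, n_norm,
                            autoregressive = TRUE) {
  probs <- cache$probs; n <- ncol(probs)
  dh <- length(cache$cells[[1]]$x) - 3L
  gg <- list(Wx = params$dec_gru$Wx * 0, Wh = params$dec_gru$Wh * 0,
             b = params$dec_gru$b * 0)
  dW <- params$dec$W * 0; db <- rep(0, 3)
  dCtx <- matrix(0, dh, n)
  dp_carry <- rep(0, 3)
  ds_carry <- rep(0, cfg$decoder_hidden)
  for (t in rev(seq_len(n))) {
    p <- probs[, t]
    dlog <- p * (dp_carry - sum(p * dp_carry))
    if (!is.null(y)) dlog <- dlog + (p - .onehot3(y[t])[, 1]) / n_norm
    dW <- dW + dlog %*% t(cache$states[, t])
    db <- db + dlog
    ds <- as.vector(crossprod(params$dec$W, dlog)) + ds_carry
    bk <- .gru_cell_bwd(cache$cells[[t]], ds, params$dec_gru, cache$dm, gg)
    gg <- bk$g
    ds_carry <- bk$dhprev
    dCtx[, t] <- bk$dx[seq_len(dh)]
    dp_carry <- if (autoregressive) bk$dx[dh + 1:3] else rep(0, 3)
  }
  list(dec_gru = gg, dec = list(W = dW, b = db), dCtx = dCtx)
}

# gradient of the Toeplitz map w.r.t. the convex kernel, given dL/dA
.toeplitz_kernel_grad <- function(kernel, dA, mask) {
  N <- nrow(dA); D <- (length(kernel) - 1L) %/% 2L
  dk <- kernel * 0
  for (n in seq_len(N)) {
    cols <- max(1L, n - D):min(N, n + D)
    cols <- cols[mask[cols]]
    if (length(cols) == 0L) next
    ki <- cols - n + D + 1L
    s <- sum(kernel[ki])
    dots <- sum(dA[n, cols] * kernel[ki])
    dk[ki] <- dk[ki] + dA[n, cols] / s - dots / s^2
  }
  dk
}

# full forward pass over one stack; X: d x n (true length, no padding)
.rcn_forward <- function(params, cfg, X, train = FALSE, y = NULL) {
  n <- ncol(X)
  rate <- if (train) cfg$recurrent_dropout else 0
  dmf <- .drop_mask(cfg$gru_hidden, rate, train)
  dmb <- .drop_mask(cfg$gru_hidden, rate, train)
  forced <- if (train && cfg$teacher_forcing && !is.null(y)) .onehot3(y) else NULL
  if (cfg$variant == "partial_seq") {
    k <- (cfg$neighborhood - 1L) %/% 2L
    idx_mat <- vapply(seq_len(n), function(i)
      pmin(pmax((i - k):(i + k), 1L), n), integer(cfg$neighborhood))
    encs <- lapply(seq_len(n), function(i) {
      .encode_fwd(params, cfg, X[, idx_mat[, i], drop = FALSE], dmf, dmb)
    })
    center <- k + 1L
    S <- vapply(encs, function(e) e$H[, center], numeric(.enc_dim(cfg)))
    logits <- params$dec$W %*% S + params$dec$b
    probs <- .softmax_cols(logits)
    return(list(probs = probs, encs = encs, idx_mat = idx_mat, S = S,
                dmf = dmf, dmb = dmb))
  }
  enc <- .encode_fwd(params, cfg, X, dmf, dmb)
  if (cfg$variant == "toeplitz") {
    kern <- toeplitzKernel(params$kernel_raw)
    A <- toeplitzAttentionMap(kern, n)
  } else if (cfg$variant == "full_seq") {
    A <- diag(n)
  } else {
    A <- globalAttentionScores(t(enc$H), params$att)
  }
  Ctx <- enc$H %*% t(A)
  dgm <- if (cfg$variant == "global_attention")
    .drop_mask(cfg$decoder_hidden, rate, train) else NULL
  dec <- if (cfg$variant == "global_attention")
    .decode_gru_fwd(params, cfg, Ctx, dgm, forced)
  else .decode_fc_fwd(params$dec, Ctx, forced)
  list(probs = dec$probs, enc = enc, A = A, Ctx = Ctx, dec = dec)
}

.rcn_backward <- function(params, cfg, X, fwd, y) {
  n <- ncol(X)
  autoreg <- !(cfg$teacher_forcing)
  if (cfg$variant == "partial_seq") {
    probs <- fwd$probs
    dlog <- probs
    dlog[cbind(y + 1L, seq_len(n))] <- dlog[cbind(y + 1L, seq_len(n))] - 1
    dlog <- dlog / n
    g <- list(dec = list(W = dlog %*% t(fwd$S), b = rowSums(dlog)))
    dS <- crossprod(params$dec$W, dlog)   # dh x n
    center <- (cfg$neighborhood - 1L) %/% 2L + 1L
    acc <- NULL
    for (i in seq_len(n)) {
      dH <- matrix(0, .enc_dim(cfg), cfg$neighborhood)
      dH[, center] <- dS[, i]
      gi <- .encode_bwd(params, cfg, X[, fwd$idx_mat[, i], drop = FALSE],
                        fwd$encs[[i]], dH)
      acc <- if (is.null(acc)) gi else .nn_add(acc, gi)
    }
    return(c(acc, g))
  }
  if (cfg$variant == "global_attention") {
    db <- .decode_gru_bwd(params, cfg, fwd$dec, y, n, autoreg)
    g <- list(dec_gru = db$dec_gru, dec = db$dec)
  } else {
    db <- .decode_fc_bwd(params$dec, fwd$dec, y, n, autoreg)
    g <- list(dec = list(W = db$dW, b = db$db))
  }
  dCtx <- db$dCtx                          # dh x n
  dH <- dCtx %*% fwd$A                     # through the context weighted sum
  dA <- crossprod(dCtx, fwd$enc$H)         # dA[i, m] = dCtx[, i] . H[, m]
  if (cfg$variant == "toeplitz") {
    kern <- toeplitzKernel(params$kernel_raw)
    dk <- .toeplitz_kernel_grad(kern, dA, rep(TRUE, n))
    g$kernel_raw <- kern * (dk - sum(dk * kern))  # softmax chain
  } else if (cfg$variant == "global_attention") {
    ga <- .global_att_bwd(params$att, fwd$enc$H, fwd$A, dA)
    g$att <- ga$g
    dH <- dH + ga$dH
  }
  c(.encode_bwd(params, cfg, X, fwd$enc, dH), g)
}

# backward through the additive attention scores; H: dh x N, A row-stochastic
.global_att_bwd <- function(att, H, A, dA) {
  N <- ncol(H)
  S1 <- att$W1 %*% H
  S2 <- att$W2 %*% H
  dW1 <- att$W1 * 0; dW2 <- att$W2 * 0; dv <- att$v * 0
  dS1 <- S1 * 0; dS2 <- S2 * 0
  for (n in seq_len(N)) {
    a <- A[n, ]
    de <- a * (dA[n, ] - sum(a * dA[n, ]))  # softmax jacobian per row
    Tn <- tanh(S1[, n] + S2)
    dv <- dv + as.vector(Tn %*% de)
    dpre <- (att$v %o% de) * (1 - Tn^2)     # da x N
    dS1[, n] <- dS1[, n] + rowSums(dpre)
    dS2 <- dS2 + dpre
  }
  dW1 <- dS1 %*% t(H)
  dW2 <- dS2 %*% t(H)
  dH <- crossprod(att$W1, dS1) + crossprod(att$W2, dS2)
  list(g = list(W1 = dW1, W2 = dW2, v = dv), dH = dH)
}

# ---- user-facing forward helpers -------------------------------------------

.features_matrix <- function(features) {
  f <- if (is(features, "FeatureSequence")) features@features else
    as.matrix(features)
  t(f)                                     # d x n
}

#' Encode a feature sequence with the recurrent encoder
#'
#' Runs the (bidirectional) GRU over the unpadded slices in evaluation mode
#' (no dropout) and returns one encoding per slice: the concatenated
#' forward/backward hidden states, of dimension `2 * gruHidden` for
#' bidirectional models. Padded positions (mask `FALSE`) are excluded from
#' the recurrence entirely and carry zero encodings, so they cannot
#' contribute to any downstream context.
#'
#' @param model an [RCNModel].
#' @param features a [FeatureSequence] or numeric matrix (slices x dims),
#'   possibly padded.
#' @param mask optional logical vector; `TRUE` marks real slices. Padding
#'   must be a suffix.
#' @return A list with `h` (matrix, slices x encoding dims) and `mask`.
#' @export
encodeSequence <- function(model, features, mask = NULL) {
  stopifnot(is(model, "RCNModel"))
  X <- .features_matrix(features)
  if (nrow(X) != model@config$feature_dim)
    stop("feature dimension ", nrow(X), " does not match model (",
         model@config$feature_dim, ")")
  n <- ncol(X)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  len <- sum(mask)
  if (len > 0L && !all(mask[seq_len(len)]))
    stop("padding must be a suffix of the sequence")
  H <- matrix(0, n, .enc_dim(model@config))
  if (len > 0L) {
    enc <- .encode_fwd(model@params, model@config, X[, seq_len(len), drop = FALSE])
    H[seq_len(len), ] <- t(enc$H)
  }
  list(h = H, mask = mask)
}

#' Per-slice class probabilities for a feature sequence
#'
#' Full evaluation-mode forward pass of the sequence model: recurrent
#' encoding, attention (per the model's variant), and autoregressive
#' decoding shallow-to-deep, where each step receives the context vector
#' concatenated with the previous step's class probabilities (a zero vector
#' at the first slice). Stacks longer than the model's `max_len` are clipped
#' to their first `max_len` slices with a warning. Ties in the argmax go to
#' the lowest class index (the shallowest stratum) for determinism.
#'
#' @param model an [RCNModel].
#' @param features a [FeatureSequence] or numeric matrix (slices x dims).
#' @param mask optional logical vector marking real slices (padding suffix).
#' @return A list with `probs` (slices x 3 row-stochastic matrix), `labels`
#'   (integer argmax codes), and `stackId`.
#' @export
predictRCN <- function(model, features, mask = NULL) {
  stopifnot(is(model, "RCNModel"))
  cfg <- model@config
  X <- .features_matrix(features)
  id <- if (is(features, "FeatureSequence")) stackId(features) else "stack"
  n_all <- ncol(X)
  if (is.null(mask)) mask <- rep(TRUE, n_all)
  len <- sum(mask)
  if (len > 0L && !all(mask[seq_len(len)]))
    stop("padding must be a suffix of the sequence")
  if (len > cfg$max_len) {
    warning("stack of ", len, " slices clipped to first ", cfg$max_len)
    len <- cfg$max_len
  }
  fwd <- .rcn_forward(model@params, cfg, X[, seq_len(len), drop = FALSE])
  probs <- matrix(0, n_all, 3)
  probs[seq_len(len), ] <- t(fwd$probs)
  labels <- rep(NA_integer_, n_all)
  labels[seq_len(len)] <- max.col(probs[seq_len(len), , drop = FALSE],
                                  ties.method = "first") - 1L
  colnames(probs) <- c("p_epidermis", "p_DEJ", "p_dermis")
  list(probs = probs, labels = labels, stackId = id, mask = mask,
       length = len)
}

#' Attention map a model assigns to a sequence of length N
#'
#' @param model an [RCNModel].
#' @param features feature sequence (required for `global_attention`, whose
#'   map depends on the encodings; for `toeplitz`/`full_seq` only the length
#'   is used).
#' @param N sequence length (ignored when `features` is given).
#' @return The `N x N` row-stochastic attention map.
#' @export
attentionMap <- function(model, features = NULL, N = NULL) {
  cfg <- model@config
  if (!is.null(features)) N <- ncol(.features_matrix(features))
  stopifnot(!is.null(N))
  switch(cfg$variant,
    toeplitz = toeplitzAttentionMap(toeplitzKernel(model@params$kernel_raw), N),
    full_seq = diag(N),
    partial_seq = stop("partial_seq models have no attention map"),
    global_attention = {
      if (is.null(features)) stop("global attention needs the features")
      enc <- encodeSequence(model, features)
      globalAttentionScores(enc$h, model@params$att)
    })
}

#' Build partial-sequence training windows
#'
#' One window per slice: the `neighborhood`-slice depth window centered on
#' it, with edge windows padded by replicating the terminal slice, paired
#' with the center slice's label.
#'
#' @param features a [FeatureSequence] or matrix (slices x dims).
#' @param labels a [StrataLabelSequence] or integer vector, same length.
#' @param neighborhood odd window length (default 3).
#' @return A list of `list(window, label)` pairs, one per slice; `window` is
#'   a `neighborhood x dims` matrix.
#' @export
makePartialSequences <- function(features, labels, neighborhood = 3L) {
  stopifnot(neighborhood %% 2L == 1L)
  f <- t(.features_matrix(features))       # n x d
  y <- .as_labels(labels)
  n <- nrow(f)
  stopifnot(length(y) == n)
  k <- (neighborhood - 1L) %/% 2L
  lapply(seq_len(n), function(i) {
    idx <- pmin(pmax((i - k):(i + k), 1L), n)
    list(window = f[idx, , drop = FALSE], label = y[i])
  })
}

# ---- training ---------------------------------------------------------------

.l1_penalty_params <- function(params, cfg) {
  mats <- list(params$enc_f$Wh)
  if (!is.null(params$enc_b)) mats <- c(mats, list(params$enc_b$Wh))
  if (!is.null(params$dec_gru)) mats <- c(mats, list(params$dec_gru$Wh))
  mats
}

.rcn_loss_eval <- function(params, cfg, X, y) {
  fwd <- .rcn_forward(params, cfg, X, train = FALSE)
  .ce_loss(fwd$probs, y)
}

#' Train a recurrent sequence model on frozen feature sequences
#'
#' Minimizes masked per-slice cross-entropy plus an L1 penalty on the
#' recurrent weight matrices, with Adam, variational recurrent dropout, and
#' gradient steps every `batch_stacks` sequences. The snapshot with the best
#' validation accuracy (ties broken by lower validation loss) is returned.
#' Sequences longer than `max_len` are clipped to their first `max_len`
#' slices. Fully reproducible given the config seed.
#'
#' @param model an [RCNModel] from [buildRCN()].
#' @param trainFeatures,valFeatures lists of [FeatureSequence] objects.
#' @param trainLabels,valLabels lists of [StrataLabelSequence] objects (or
#'   integer vectors), aligned with the feature lists.
#' @param verbose print per-epoch progress.
#' @return A list with `model` (trained, best snapshot) and `history`
#'   (data.frame: epoch, train_loss, val_loss, val_accuracy; train_loss
#'   includes the L1 term, validation losses do not).
#' @export
trainRCN <- function(model, trainFeatures, trainLabels,
                     valFeatures, valLabels, verbose = FALSE) {
  stopifnot(is(model, "RCNModel"))
  cfg <- model@config
  if (length(valFeatures) == 0L)
    stop("a validation set is required for snapshot selection")
  if (length(trainFeatures) == 0L) stop("empty training set")
  stopifnot(length(trainFeatures) == length(trainLabels),
            length(valFeatures) == length(valLabels))
  prep <- function(f, l) {
    X <- .features_matrix(f)
    y <- .as_labels(l)
    stopifnot(ncol(X) == length(y))
    n <- min(ncol(X), cfg$max_len)
    list(X = X[, seq_len(n), drop = FALSE], y = y[seq_len(n)])
  }
  tr <- mapply(prep, trainFeatures, trainLabels, SIMPLIFY = FALSE)
  va <- mapply(prep, valFeatures, valLabels, SIMPLIFY = FALSE)
  params <- model@params
  opt <- .adam_init(params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  best <- list(acc = -Inf, loss = Inf, params = params)
  l1_term <- function(p) {
    if (cfg$l1_recurrent <= 0) return(0)
    cfg$l1_recurrent * sum(vapply(.l1_penalty_params(p, cfg),
                                  function(m) sum(abs(m)), numeric(1)))
  }
  add_l1_grad <- function(g, p) {
    if (cfg$l1_recurrent <= 0) return(g)
    g$enc_f$Wh <- g$enc_f$Wh + cfg$l1_recurrent * sign(p$enc_f$Wh)
    if (!is.null(p$enc_b))
      g$enc_b$Wh <- g$enc_b$Wh + cfg$l1_recurrent * sign(p$enc_b$Wh)
    if (!is.null(p$dec_gru))
      g$dec_gru$Wh <- g$dec_gru$Wh + cfg$l1_recurrent * sign(p$dec_gru$Wh)
    g
  }
  .with_seed(cfg$seed + 17L, {
    nt <- length(tr)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(nt)
      tl <- 0; nb <- 0L
      acc_g <- NULL; acc_k <- 0L
      for (si in ord) {
        X <- tr[[si]]$X; y <- tr[[si]]$y
        fwd <- .rcn_forward(params, cfg, X, train = TRUE, y = y)
        tl <- tl + .ce_loss(fwd$probs, y); nb <- nb + 1L
        g <- .rcn_backward(params, cfg, X, fwd, y)
        acc_g <- if (is.null(acc_g)) g else .nn_add(acc_g, g)
        acc_k <- acc_k + 1L
        if (acc_k == cfg$batch_stacks || si == ord[nt]) {
          acc_g <- .nn_map(acc_g, function(x) x / acc_k)
          acc_g <- add_l1_grad(acc_g, params)
          if (cfg$lr > 0) {
            st <- .adam_step(params, acc_g, opt, cfg$lr)
            params <- st$params; opt <- st$state
          }
          acc_g <- NULL; acc_k <- 0L
        }
      }
      vl <- 0; vacc_n <- 0L; vacc_c <- 0L
      for (s in va) {
        fwd <- .rcn_forward(params, cfg, s$X, train = FALSE)
        vl <- vl + .ce_loss(fwd$probs, s$y)
        pred <- max.col(t(fwd$probs), ties.method = "first") - 1L
        vacc_c <- vacc_c + sum(pred == s$y)
        vacc_n <- vacc_n + length(s$y)
      }
      vl <- vl / length(va)
      vacc <- vacc_c / vacc_n
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_loss = tl / nb + l1_term(params),
        val_loss = vl, val_accuracy = vacc))
      if (vacc > best$acc || (vacc == best$acc && vl < best$loss))
        best <- list(acc = vacc, loss = vl, params = params)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val_acc %.3f",
                        epoch, tl / nb, vl, vacc))
    }
  })
  model@params <- best$params
  model@trained <- TRUE
  list(model = model, history = hist)
}
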