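# Internal tiny-CNN forward/backward passes over batches of single-channel
# images. A batch is an array H x W x (B * C) with channel c of image b at
# slice (b - 1) * C + c (1-based); the compiled kernels in src/nn_ops.cpp do
# the convolution and pooling work.

.cnn_init_params <- function(channels, embedding_dim) {
  cin <- c(1L, channels[-length(channels)])
  conv <- lapply(seq_along(channels), function(l) {
    fan_in <- 9 * cin[l]
    list(W = .glorot(channels[l], fan_in), b = rep(0, channels[l]))
  })
  list(conv = conv,
       emb = list(W = .glorot(embedding_dim, channels[length(channels)]),
                  b = rep(0, embedding_dim)),
       head = list(W = .glorot(3L, embedding_dim), b = rep(0, 3L)))
}

# images: list of H x W matrices -> H x W x B array (C = 1)
.cnn_batch_array <- function(images) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(h, w, length(images)))
}

.cnn_forward <- function(params, X, B, channels) {
  acts <- list()    # per layer: input, pre-relu, relu (pre-pool)
  a <- X
  cin <- 1L
  for (l in seq_along(channels)) {
    z <- cpp_conv3_forward(a, B, cin, params$conv[[l]]$W, params$conv[[l]]$b)
    r <- pmax(z, 0)
    p <- cpp_avgpool2_forward(r)
    acts[[l]] <- list(input = a, z = z)
    a <- p
    cin <- channels[l]
  }
  C4 <- channels[length(channels)]
  hw <- dim(a)[1] * dim(a)[2]
  # global average pool: C4 x B
  G <- matrix(colMeans(matrix(a, nrow = hw)), nrow = C4)
  emb <- params$emb$W %*% G + params$emb$b          # linear embedding
  act <- pmax(emb, 0)
  logits <- params$head$W %*% act + params$head$b
  probs <- .softmax_cols(logits)
  list(probs = probs, emb = emb, act = act, G = G, pooled = a, acts = acts)
}

.cnn_backward <- function(params, fwd, X, B, channels, y) {
  n <- length(y)
  dlogits <- fwd$probs
  dlogits[cbind(y + 1L, seq_len(n))] <- dlogits[cbind(y + 1L, seq_len(n))] - 1
  dlogits <- dlogits / n
  g <- list(conv = vector("list", length(channels)))
  g$head <- list(W = dlogits %*% t(fwd$act), b = rowSums(dlogits))
  dact <- t(params$head$W) %*% dlogits
  demb <- dact * (fwd$emb > 0)
  g$emb <- list(W = demb %*% t(fwd$G), b = rowSums(demb))
  dG <- t(params$emb$W) %*% demb                    # C4 x B
  pd <- dim(fwd$pooled)
  hw <- pd[1] * pd[2]
  # spread the global-average gradient uniformly over spatial positions
  da <- array(rep(as.vector(dG), each = hw) / hw, dim = pd)
  cin <- c(1L, channels[-length(channels)])
  for (l in rev(seq_along(channels))) {
    z <- fwd$acts[[l]]$z
    dr <- cpp_avgpool2_backward(da, dim(z)[1], dim(z)[2])
    dz <- dr * (z > 0)
    bk <- cpp_conv3_backward(fwd$acts[[l]]$input, B, cin[l],
                             params$conv[[l]]$W, dz)
    g$conv[[l]] <- list(W = bk$dW, b = as.vector(bk$db))
    da <- bk$dX
  }
  g
}
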