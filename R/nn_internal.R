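# Internal optimizer and array helpers shared by the slice encoder and the
# recurrent sequence models. Parameters and gradients are nested lists of
# numeric arrays with identical shapes.

# walks two parallel nested lists; matches elements by name when both sides
# are named (gradient lists are not guaranteed to share the params' order)
.nn_map2 <- function(a, b, f) {
  if (is.list(a)) {
    nm <- names(a)
    out <- if (!is.null(nm) && !is.null(names(b)))
      lapply(nm, function(k) .nn_map2(a[[k]], b[[k]], f))
    else mapply(.nn_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- nm
    out
  } else f(a, b)
}

.nn_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, .nn_map, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}

.nn_zeros_like <- function(params) .nn_map(params, function(p) p * 0)

.adam_init <- function(params) {
  list(m = .nn_zeros_like(params), v = .nn_zeros_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .nn_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .nn_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .nn_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- .nn_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

.nn_add <- function(a, b) .nn_map2(a, b, `+`)

# Glorot-uniform initialization for a fan_in x fan_out pair
.glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

.softmax_cols <- function(Z) {
  Z <- Z - matrix(apply(Z, 2, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(E), ncol(E), byrow = TRUE)
}

# cross-entropy loss and logit gradient for class-probability columns
.ce_loss <- function(probs, y, eps = 1e-12) {
  -mean(log(pmax(probs[cbind(y + 1L, seq_along(y))], eps)))
}
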