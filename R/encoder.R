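#' Configuration for the convolutional slice encoder
#'
#' The default backbone is a small 4-block convnet (3x3 convolutions with
#' ReLU and 2x2 average pooling, then global average pooling) topped by a
#' 256-neuron fully connected embedding layer and a 3-class softmax head.
#' When the trained network is used as a frozen feature extractor, the
#' classifier head and the non-linearity on the embedding layer are dropped,
#' so features are the linear pre-activations of the 256-d layer. A deeper
#' `tiny_cnn_wide` backbone doubles the channel widths.
#'
#' @param backbone `"tiny_cnn"` (default) or `"tiny_cnn_wide"`.
#' @param embeddingDim embedding width (at least 8; default 256).
#' @param augmentation list of flags/magnitudes for training-time
#'   augmentation: `rotate` (max degrees), `zoom`, `shear`, `stretch`
#'   (max fractional change), `hflip`, `vflip` (logical). Set `enabled =
#'   FALSE` to disable all.
#' @param lr Adam learning rate.
#' @param epochs training epochs over the slice set.
#' @param batchSize minibatch size in slices.
#' @param seed integer seed for initialization, shuffling and augmentation.
#' @return A list of class `EncoderConfig`.
#' @export
encoderConfig <- function(backbone = c("tiny_cnn", "tiny_cnn_wide"),
                          embeddingDim = 256L,
                          augmentation = list(enabled = TRUE, rotate = 10,
                                              zoom = 0.1, shear = 0.1,
                                              stretch = 0.1, hflip = TRUE,
                                              vflip = TRUE),
                          lr = 2e-3, epochs = 25L, batchSize = 32L,
                          seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(embeddingDim >= 8L, lr >= 0, epochs >= 1L, batchSize >= 1L)
  channels <- switch(backbone,
    tiny_cnn = c(8L, 16L, 32L, 32L),
    tiny_cnn_wide = c(16L, 32L, 64L, 64L))
  structure(list(backbone = backbone, embedding_dim = as.integer(embeddingDim),
                 input_channels = 1L, channels = channels,
                 augmentation = augmentation, lr = lr,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 seed = as.integer(seed)),
            class = "EncoderConfig")
}

#' Build an untrained slice encoder
#'
#' @param config an [encoderConfig()]; an unknown backbone name is an error.
#' @return A [SliceEncoder] with randomly initialized weights (seeded from
#'   `config$seed`).
#' @export
buildEncoder <- function(config = encoderConfig()) {
  if (!inherits(config, "EncoderConfig"))
    stop("config must be created by encoderConfig()")
  params <- .with_seed(config$seed,
                       .cnn_init_params(config$channels, config$embedding_dim))
  new("SliceEncoder", config = unclass(config), params = params, trained = FALSE)
}

.check_slice <- function(image) {
  if (!is.matrix(image))
    stop("slices must be single-channel (a numeric matrix); got ",
         paste(dim(image), collapse = "x"))
  image
}

# bilinear sampling of img at an affine map around the image center;
# out-of-range samples clamp to the nearest edge pixel
.affine_warp <- function(img, M) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yi <- matrix(seq_len(h) - cy, h, w)
  xi <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  ys <- M[1, 1] * yi + M[1, 2] * xi + cy
  xs <- M[2, 1] * yi + M[2, 2] * xi + cx
  ys <- pmin(pmax(ys, 1), h)
  xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1); x0 <- pmin(floor(xs), w - 1)
  fy <- ys - y0; fx <- xs - x0
  idx <- function(y, x) img[cbind(as.vector(y), as.vector(x))]
  v <- (1 - fy) * (1 - fx) * idx(y0, x0) + fy * (1 - fx) * idx(y0 + 1, x0) +
    (1 - fy) * fx * idx(y0, x0 + 1) + fy * fx * idx(y0 + 1, x0 + 1)
  matrix(v, h, w)
}

#' Randomly augment a slice image
#'
#' One random composition of the enabled transforms: shear, zoom, rotation,
#' anisotropic stretch, and horizontal/vertical flips. Geometric transforms
#' are applied as a single affine warp with bilinear interpolation about the
#' image center, so the output has the same shape as the input. Parameters
#' are drawn from the caller's RNG stream. With everything disabled the input
#' is returned unchanged.
#'
#' @param image numeric matrix (single-channel slice).
#' @param config an [encoderConfig()] whose `augmentation` element sets the
#'   magnitudes.
#' @return The augmented image.
#' @export
augmentSlice <- function(image, config = encoderConfig()) {
  .check_slice(image)
  aug <- config$augmentation
  if (!isTRUE(aug$enabled)) return(image)
  if (isTRUE(aug$hflip) && stats::runif(1) < 0.5) image <- image[, ncol(image):1]
  if (isTRUE(aug$vflip) && stats::runif(1) < 0.5) image <- image[nrow(image):1, ]
  theta <- if (is.null(aug$rotate)) 0 else
    stats::runif(1, -aug$rotate, aug$rotate) * pi / 180
  zoom <- if (is.null(aug$zoom)) 1 else 1 + stats::runif(1, -aug$zoom, aug$zoom)
  stretch <- if (is.null(aug$stretch)) 1 else
    1 + stats::runif(1, -aug$stretch, aug$stretch)
  shear <- if (is.null(aug$shear)) 0 else stats::runif(1, -aug$shear, aug$shear)
  if (theta == 0 && zoom == 1 && stretch == 1 && shear == 0) return(image)
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  S <- matrix(c(1 / (zoom * stretch), shear, 0, stretch / zoom), 2, 2)
  .affine_warp(image, S %*% R)
}

#' Train the slice encoder on labeled slices
#'
#' Image-wise 3-class training with cross-entropy loss and Adam, optional
#' augmentation of each training slice per epoch, and best-validation
#' snapshot selection: the returned encoder carries the weights of the epoch
#' with the highest validation accuracy. The learning rate follows a step
#' schedule (multiplied by 0.2 after 60% and again after 85% of the epochs)
#' so late training settles instead of oscillating.
#'
#' @param encoder a [SliceEncoder] from [buildEncoder()].
#' @param trainImages,valImages lists of slice matrices.
#' @param trainLabels,valLabels integer vectors of codes in {0, 1, 2}.
#' @return A list with `encoder` (trained, best snapshot) and `history`
#'   (data.frame: epoch, train_loss, val_loss, val_accuracy).
#' @export
trainEncoder <- function(encoder, trainImages, trainLabels,
                         valImages, valLabels) {
  stopifnot(is(encoder, "SliceEncoder"))
  if (length(trainImages) == 0L) stop("empty training set")
  if (length(trainImages) != length(trainLabels))
    stop("trainImages and trainLabels lengths differ")
  if (length(unique(trainLabels)) < 2L)
    stop("training slices contain a single class; at least 2 are required")
  if (length(valImages) == 0L) stop("empty validation set")
  cfg <- encoder@config
  channels <- cfg$channels
  params <- encoder@params
  opt <- .adam_init(params)
  y_tr <- as.integer(trainLabels)
  y_val <- as.integer(valLabels)
  Xval <- .cnn_batch_array(valImages)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  best <- list(acc = -Inf, loss = Inf, params = params)
  .with_seed(cfg$seed + 1L, {
    n <- length(trainImages)
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$lr *
        if (epoch > 0.85 * cfg$epochs) 0.04
        else if (epoch > 0.6 * cfg$epochs) 0.2
        else 1
      ord <- sample.int(n)
      tl <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batchSize)) {
        idx <- ord[start:min(start + cfg$batchSize - 1L, n)]
        imgs <- lapply(trainImages[idx], function(im)
          if (isTRUE(cfg$augmentation$enabled)) augmentSlice(im, cfg) else im)
        X <- .cnn_batch_array(imgs)
        fwd <- .cnn_forward(params, X, length(idx), channels)
        y <- y_tr[idx]
        tl <- tl + .ce_loss(fwd$probs, y); nb <- nb + 1L
        g <- .cnn_backward(params, fwd, X, length(idx), channels, y)
        if (cfg$lr > 0) {
          st <- .adam_step(params, g, opt, lr)
          params <- st$params; opt <- st$state
        }
      }
      vfwd <- .cnn_forward(params, Xval, length(valImages), channels)
      vloss <- .ce_loss(vfwd$probs, y_val)
      vacc <- mean(max.col(t(vfwd$probs), ties.method = "first") - 1L == y_val)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                     val_loss = vloss, val_accuracy = vacc))
      if (vacc > best$acc || (vacc == best$acc && vloss < best$loss))
        best <- list(acc = vacc, loss = vloss, params = params)
    }
  })
  encoder@params <- best$params
  encoder@trained <- TRUE
  list(encoder = encoder, history = hist)
}

#' Extract frozen per-slice features from a stack
#'
#' Runs the encoder deterministically (no augmentation, weights untouched)
#' and returns the linear 256-d embedding of every slice, in slice order.
#'
#' @param encoder a trained [SliceEncoder].
#' @param stack an [RCMStack], or a list of slice matrices.
#' @return A [FeatureSequence] with one row per slice.
#' @export
extractFeatures <- function(encoder, stack) {
  stopifnot(is(encoder, "SliceEncoder"))
  slices <- if (is(stack, "RCMStack")) stack@slices else stack
  lapply(slices, .check_slice)
  id <- if (is(stack, "RCMStack")) stackId(stack) else "stack"
  X <- .cnn_batch_array(slices)
  fwd <- .cnn_forward(encoder@params, X, length(slices), encoder@config$channels)
  FeatureSequence(t(fwd$emb), stackId = id)
}

#' Per-slice class probabilities from the encoder alone
#'
#' The single-image baseline: classify each slice independently with the
#' CNN's own softmax head, ignoring stack order.
#'
#' @inheritParams extractFeatures
#' @return Numeric matrix, slices x 3 (epidermis, DEJ, dermis).
#' @export
classifySlices <- function(encoder, stack) {
  stopifnot(is(encoder, "SliceEncoder"))
  slices <- if (is(stack, "RCMStack")) stack@slices else stack
  X <- .cnn_batch_array(slices)
  fwd <- .cnn_forward(encoder@params, X, length(slices), encoder@config$channels)
  t(fwd$probs)
}

#' Save or load a model checkpoint
#'
#' Checkpoints are single RDS files holding the model object (a
#' [SliceEncoder] or [RCNModel]).
#'
#' @param model the model object.
#' @param path checkpoint file path.
#' @return `path` invisibly (`saveCheckpoint`); the model (`loadCheckpoint`).
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
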