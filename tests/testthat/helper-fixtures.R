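# shared fixtures: all built in code, seeded

random_features <- function(n, d = 8L, seed = 1L, stackId = "stack") {
  set.seed(seed)
  FeatureSequence(matrix(rnorm(n * d), n, d), stackId = stackId)
}

tiny_rcn_config <- function(variant = "toeplitz", D = 1L, ...) {
  rcnConfig(variant = variant, D = D, gruHidden = 4L, featureDim = 6L,
            attnDim = 3L, decoderHidden = 4L, recurrentDropout = 0,
            l1Recurrent = 0, epochs = 5L, seed = 7L, ...)
}

# a depth-structured toy feature task: class identity leaks into the features
# through a class-dependent mean, so tiny sequence models can learn it
toy_feature_dataset <- function(nStacks, d = 6L, nSlices = 12L, seed = 1L,
                                noise = 0.8) {
  set.seed(seed)
  protos <- matrix(rnorm(3 * d, sd = 1.5), 3, d)
  feats <- list(); labs <- list()
  for (k in seq_len(nStacks)) {
    b1 <- sample(3:6, 1); b2 <- sample((b1 + 2):(nSlices - 2), 1)
    y <- ifelse(seq_len(nSlices) - 1 < b1, 0L,
                ifelse(seq_len(nSlices) - 1 < b2, 1L, 2L))
    f <- protos[y + 1L, ] + matrix(rnorm(nSlices * d, sd = noise), nSlices, d)
    id <- sprintf("toy%03d", k)
    feats[[k]] <- FeatureSequence(f, stackId = id)
    labs[[k]] <- StrataLabelSequence(y, stackId = id)
  }
  list(features = feats, labels = labs)
}

# independent brute-force inconsistency counter (oracle)
oracle_inconsistencies <- function(x) {
  bad <- list(c(0, 2), c(1, 0), c(2, 0), c(2, 1))
  total <- 0L
  counts <- integer(4)
  if (length(x) >= 2) {
    for (i in seq_len(length(x) - 1)) {
      for (j in seq_along(bad)) {
        if (x[i] == bad[[j]][1] && x[i + 1] == bad[[j]][2]) {
          counts[j] <- counts[j] + 1L
          total <- total + 1L
        }
      }
    }
  }
  list(epi_to_derm = counts[1], dej_to_epi = counts[2],
       derm_to_epi = counts[3], derm_to_dej = counts[4], total = total)
}

# independent confusion-matrix metrics (oracle)
oracle_classification <- function(truth, pred) {
  acc <- mean(truth == pred)
  sens <- spec <- numeric(3)
  for (c in 0:2) {
    tp <- sum(truth == c & pred == c)
    fn <- sum(truth == c & pred != c)
    fp <- sum(truth != c & pred == c)
    tn <- sum(truth != c & pred != c)
    sens[c + 1] <- tp / (tp + fn)
    spec[c + 1] <- tn / (tn + fp)
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec)
}

# central-difference gradient of a scalar function over a nested param list
numeric_gradient <- function(f, params, eps = 1e-6) {
  assign_in <- function(lst, path, i, val) {
    if (length(path) == 0) { lst[i] <- val; return(lst) }
    lst[[path[1]]] <- assign_in(lst[[path[1]]], path[-1], i, val)
    lst
  }
  out <- rapply(params, function(p) p * 0, how = "replace")
  walk <- function(path) {
    p <- params
    for (k in path) p <- p[[k]]
    for (i in seq_along(p)) {
      up <- f(assign_in(params, path, i, p[i] + eps))
      dn <- f(assign_in(params, path, i, p[i] - eps))
      out <<- assign_in(out, path, i, (up - dn) / (2 * eps))
    }
  }
  rec <- function(obj, path) {
    if (is.list(obj)) for (k in names(obj)) rec(obj[[k]], c(path, k))
    else walk(path)
  }
  rec(params, character())
  out
}

max_param_diff <- function(a, b) {
  m <- 0
  rec <- function(x, y) {
    if (is.list(x)) for (k in names(x)) rec(x[[k]], y[[k]])
    else m <<- max(m, max(abs(x - y)))
  }
  rec(a, b)
  m
}
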