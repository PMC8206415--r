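test_that("boundary placement matches the target class fractions in expectation", {
  cfg <- syntheticDatasetConfig(nSlicesRange = c(50L, 50L))
  set.seed(123)
  specs <- replicate(2000, sampleStackSpec(cfg), simplify = FALSE)
  b1 <- vapply(specs, `[[`, integer(1), "b1")
  b2 <- vapply(specs, `[[`, integer(1), "b2")
  # expectations forced by construction: 0.44 * 50 = 22, 0.78 * 50 = 39
  expect_equal(mean(b1), 22, tolerance = 0.05)
  expect_equal(mean(b2), 39, tolerance = 0.05)
  expect_true(all(b1 >= 1 & b1 < b2 & b2 <= 49))
})

test_that("degenerate class-fraction targets are rejected", {
  expect_error(syntheticDatasetConfig(classFractions = c(1, 0, 0)),
               "classFractions")
  cfg <- syntheticDatasetConfig(classFractions = c(0.98, 0.01, 0.01),
                                nSlicesRange = c(20L, 20L))
  set.seed(1)
  expect_error(sampleStackSpec(cfg), "force")
})

test_that("spec sampling and stack generation are seed-deterministic", {
  cfg <- syntheticDatasetConfig(imageSize = c(16L, 16L))
  s1 <- local({ set.seed(7); sampleStackSpec(cfg) })
  s2 <- local({ set.seed(7); sampleStackSpec(cfg) })
  expect_identical(s1, s2)
  g1 <- generateStack(s1)
  g2 <- generateStack(s2)
  expect_identical(g1$stack@slices, g2$stack@slices)   # bit-identical
  expect_identical(g1$labels@labels, g2$labels@labels)
})

test_that("generated labels and boundaries are forced by b1/b2", {
  cfg <- syntheticDatasetConfig(nSlicesRange = c(20L, 20L),
                                imageSize = c(16L, 16L), axialStepUm = 2.5)
  spec <- local({ set.seed(3); sampleStackSpec(cfg) })
  spec$b1 <- 8L; spec$b2 <- 14L
  gen <- generateStack(spec)
  expect_equal(as.vector(table(gen$labels@labels)), c(8, 6, 6))
  expect_equal(gen$boundaries@epiDejUm, 8 * 2.5)
  expect_equal(gen$boundaries@dejDermUm, 14 * 2.5)
  # monotone by construction, zero inconsistent transitions
  expect_false(is.unsorted(gen$labels@labels))
  expect_equal(countInconsistencies(gen$labels)$total, 0L)
})

test_that("contrast decays with depth only when the decay rate is positive", {
  cfg <- syntheticDatasetConfig(nSlicesRange = c(30L, 30L),
                                imageSize = c(32L, 32L), noiseSigma = 0)
  spec <- local({ set.seed(11); sampleStackSpec(cfg) })
  spec$b1 <- 5L; spec$b2 <- 10L
  spec0 <- spec; spec0$contrastDecayRate <- 0
  specd <- spec; specd$contrastDecayRate <- 0.15
  mean_abs <- function(g) vapply(g$stack@slices[11:30],
                                 function(m) mean(abs(m - mean(m))),
                                 numeric(1))
  trend <- function(v) unname(stats::coef(stats::lm(v ~ seq_along(v)))[2])
  expect_lt(trend(mean_abs(generateStack(specd))), -1e-3)
  expect_lt(abs(trend(mean_abs(generateStack(spec0)))), 1e-3)
})

test_that("pure epidermis and dermis textures are linearly separable", {
  ds <- generateDataset(syntheticDatasetConfig(nStacks = 15, subjects = 5,
                                               seed = 21))
  imgs <- list(); y <- integer()
  for (g in ds$stacks) {
    keep <- g$labels@labels != 1L
    imgs <- c(imgs, g$stack@slices[keep])
    y <- c(y, g$labels@labels[keep])
  }
  f <- t(vapply(imgs, function(m)
    c(mean(m), stats::var(as.vector(m)), mean(abs(diff(m)))), numeric(3)))
  fit <- suppressWarnings(stats::glm((y == 2L) ~ f, family = stats::binomial))
  acc <- mean((fit$fitted.values > 0.5) == (y == 2L))
  expect_gte(acc, 0.95)
})

test_that("dataset splits are subject-wise and reproducible", {
  cfg <- syntheticDatasetConfig(nStacks = 30, subjects = 10,
                                splitFractions = c(0.5, 0.2, 0.3),
                                imageSize = c(16L, 16L), seed = 5)
  ds <- generateDataset(cfg, render = FALSE)
  man <- ds$manifest
  per_split <- split(man$subject_id, man$split)
  expect_equal(length(unique(per_split$train)), 5L)
  expect_equal(length(unique(per_split$val)), 2L)
  expect_equal(length(unique(per_split$test)), 3L)
  expect_equal(length(Reduce(intersect, lapply(per_split, unique))), 0L)
  ds2 <- generateDataset(cfg, render = FALSE)
  expect_identical(man, ds2$manifest)
  expect_warning(
    generateDataset(syntheticDatasetConfig(nStacks = 3, subjects = 1,
                                           imageSize = c(16L, 16L)),
                    render = FALSE),
    "fewer subjects")
  expect_error(syntheticDatasetConfig(splitFractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(syntheticDatasetConfig(splitFractions = c(0, 0.5, 0.5)),
               "training fraction")
})

test_that("label corruption flips only near boundaries at the right rate", {
  y <- c(rep(0L, 10), rep(1L, 10), rep(2L, 10))
  set.seed(2)
  expect_identical(corruptLabels(y, flipProb = 0), y)
  # flipProb 1, window 1: exactly the boundary-adjacent slices swap class
  flipped <- corruptLabels(y, flipProb = 1, window = 1L)
  expect_equal(flipped[10], 1L)   # last epidermis slice -> DEJ
  expect_equal(flipped[11], 0L)   # first DEJ slice -> epidermis
  expect_equal(flipped[20], 2L)
  expect_equal(flipped[21], 1L)
  expect_equal(flipped[-c(10, 11, 20, 21)], y[-c(10, 11, 20, 21)])
  # binomial oracle: eligible = 2 boundaries * 2*window slices
  window <- 2L; p <- 0.3; reps <- 4000
  eligible <- 2 * 2 * window
  set.seed(31)
  flips <- replicate(reps, sum(corruptLabels(y, p, window) != y))
  se <- sqrt(p * (1 - p) * eligible / reps)
  expect_lt(abs(mean(flips) - p * eligible), 3 * se)
})
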