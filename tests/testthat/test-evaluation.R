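test_that("inconsistency counts match the brute-force oracle", {
  expect_equal(countInconsistencies(c(0, 0, 1, 1, 2, 2))$total, 0L)
  r <- countInconsistencies(c(0, 2, 1, 0))
  expect_equal(r$epi_to_derm, 1L)
  expect_equal(r$derm_to_dej, 1L)
  expect_equal(r$dej_to_epi, 1L)
  expect_equal(r$derm_to_epi, 0L)
  expect_equal(r$total, 3L)
  set.seed(99)
  for (i in 1:1000) {
    x <- sample(0:2, sample(1:15, 1), replace = TRUE)
    expect_identical(countInconsistencies(x), oracle_inconsistencies(x))
  }
})

test_that("classification report reproduces hand-computed metrics", {
  rep1 <- classificationReport(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 2))
  expect_equal(rep1$accuracy, 0.8)
  expect_equal(unname(rep1$sensitivity), c(0.5, 1, 1))
  expect_equal(unname(rep1$specificity), c(1, 2 / 3, 1))
  rep2 <- classificationReport(c(0, 1, 2), c(0, 1, 2))
  expect_equal(rep2$accuracy, 1)
  expect_equal(unname(rep2$sensitivity), rep(1, 3))
  expect_equal(unname(rep2$specificity), rep(1, 3))
  # class absent from the truth: undefined sensitivity, not zero
  rep3 <- classificationReport(c(0, 0, 2), c(0, 0, 2))
  expect_true(is.nan(rep3$sensitivity[["DEJ"]]))
  expect_error(classificationReport(c(0, 1), c(0, 1, 2)), "lengths differ")
})

test_that("classification report agrees with an independent oracle", {
  set.seed(7)
  for (i in 1:500) {
    n <- sample(5:40, 1)
    t <- sample(0:2, n, replace = TRUE)
    p <- sample(0:2, n, replace = TRUE)
    got <- classificationReport(t, p)
    want <- oracle_classification(t, p)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(unname(got$sensitivity), want$sensitivity)
    expect_equal(unname(got$specificity), want$specificity)
  }
})

test_that("boundary MAE pairs stacks, excludes absents, and is symmetric", {
  be <- function(id, a, b) BoundaryEstimate(a, b, stackId = id)
  est <- list(be("s1", 9, 15), be("s2", 12, 21), be("s3", 6, NA))
  tru <- list(be("s1", 9, 15), be("s2", 9, 24), be("s3", 9, 18))
  r <- boundaryMAE(est, tru)
  expect_equal(r$mae_epi_dej_um, mean(c(0, 3, 3)))
  expect_equal(r$mae_dej_derm_um, mean(c(0, 3)))
  expect_equal(unname(r$excluded), c(0L, 1L))
  # signed errors retained: +3 and -3 average to zero
  expect_equal(mean(r$errors$epi_dej_um[2:3] * c(1, -1)), 3)
  r2 <- boundaryMAE(tru, est)
  expect_equal(r2$mae_epi_dej_um, r$mae_epi_dej_um)
  expect_equal(r2$mae_dej_derm_um, r$mae_dej_derm_um)
  expect_true(r$mae_epi_dej_um >= 0)
  expect_error(boundaryMAE(list(be("x", 1, 2)), list(be("y", 1, 2))),
               "overlapping")
})

test_that("evaluateRun composes the three surfaces correctly", {
  cfg <- syntheticDatasetConfig(nStacks = 20, subjects = 8,
                                imageSize = c(16L, 16L), seed = 3)
  ds <- generateDataset(cfg, render = FALSE)
  man <- ds$manifest
  labels <- lapply(ds$stacks, `[[`, "labels")
  names(labels) <- man$stack_id
  make_tab <- function(lab_fun) {
    do.call(rbind, lapply(man$stack_id, function(id) {
      y <- strataLabels(labels[[id]])
      n <- length(y)
      probs <- matrix(0, n, 3)
      yy <- lab_fun(y)
      probs[cbind(seq_len(n), yy + 1L)] <- 1
      data.frame(stack_id = id, slice_index = 0:(n - 1),
                 depth_um = (0:(n - 1)) * 3,
                 p_epidermis = probs[, 1], p_DEJ = probs[, 2],
                 p_dermis = probs[, 3], argmax_label = yy,
                 postprocessed_label = as.integer(enforceConsistency(yy)),
                 stringsAsFactors = FALSE)
    }))
  }
  # perfect predictor: accuracy 1, zero inconsistencies, zero MAE
  perfect <- make_tab(identity)
  rep1 <- evaluateRun(perfect, labels, man)
  expect_equal(rep1$classification$accuracy, 1)
  expect_equal(rep1$consistency_raw, 0L)
  expect_equal(rep1$consistency_post, 0L)
  expect_equal(rep1$boundaries$mae_epi_dej_um, 0)
  expect_equal(rep1$boundaries$mae_dej_derm_um, 0)
  # corrupted predictor: raw inconsistencies > 0, post-processed = 0
  set.seed(14)
  noisy <- make_tab(function(y) corruptLabels(y, flipProb = 0.3, window = 2L))
  rep2 <- evaluateRun(noisy, labels, man)
  expect_gt(rep2$consistency_raw, 0L)
  expect_equal(rep2$consistency_post, 0L)
  # JSON serialization parses and carries all three metric blocks
  path <- tempfile(fileext = ".json")
  evaluateRun(perfect, labels, man, path = path)
  parsed <- jsonlite::read_json(path)
  expect_true(all(c("classification", "consistency_raw", "boundaries")
                  %in% names(parsed)))
  # missing stacks are reported but evaluation continues
  part <- perfect[perfect$stack_id != man$stack_id[1], ]
  expect_warning(rep3 <- evaluateRun(part, labels, man), "no predictions")
  expect_equal(rep3$missing_stacks, man$stack_id[1])
  expect_error(evaluateRun(perfect[0, ], labels, man))
})
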