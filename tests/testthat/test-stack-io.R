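test_that("natural sort orders embedded numbers numerically", {
  expect_equal(naturalSort(c("s02.png", "s10.png", "s1.png")),
               c("s1.png", "s02.png", "s10.png"))
  expect_equal(naturalSort(c("slice100", "slice20", "slice3")),
               c("slice3", "slice20", "slice100"))
  # total and deterministic: idempotent and permutation-invariant
  set.seed(4)
  names <- paste0("im", sample(1:500, 40), "_", sample(letters, 40, TRUE),
                  ".tif")
  s1 <- naturalSort(names)
  s2 <- naturalSort(sample(names))
  expect_identical(s1, s2)
  expect_identical(naturalSort(s1), s1)
})

test_that("multi-page TIFF stacks round-trip losslessly at 8 and 16 bit", {
  spec <- local({
    set.seed(2)
    sampleStackSpec(syntheticDatasetConfig(nSlicesRange = c(20L, 20L),
                                           imageSize = c(32L, 32L)))
  })
  gen <- generateStack(spec)
  path16 <- tempfile(fileext = ".tiff")
  writeStack(gen$stack, path16, bitsPerSample = 16L)
  rt <- readStack(path16, axialStep = 3)
  expect_equal(nSlices(rt), 20L)
  expect_equal(sliceDepths(rt), seq(0, 57, by = 3))
  for (i in seq_len(20)) expect_equal(rt[[i]], gen$stack[[i]], tolerance = 0)
  # 8-bit: quantize first, then the write/read must be exact
  st8 <- gen$stack
  st8@slices <- lapply(st8@slices, function(m) round(m * 255) / 255)
  path8 <- tempfile(fileext = ".tiff")
  writeStack(st8, path8, bitsPerSample = 8L)
  rt8 <- readStack(path8, axialStep = 3)
  for (i in seq_len(20)) expect_equal(rt8[[i]], st8[[i]], tolerance = 0)
})

test_that("directory stacks use natural slice order and channel-mean", {
  dir <- tempfile()
  dir.create(dir)
  imgs <- list(s1 = matrix(0.1, 8, 8), s02 = matrix(0.5, 8, 8),
               s10 = matrix(0.9, 8, 8))
  png::writePNG(imgs$s02, file.path(dir, "s02.png"))
  png::writePNG(imgs$s10, file.path(dir, "s10.png"))
  png::writePNG(imgs$s1, file.path(dir, "s1.png"))
  st <- readStack(dir, axialStep = 1.5)
  expect_equal(nSlices(st), 3L)
  # 8-bit PNG quantization: compare to within one gray level
  expect_lt(abs(st[[1]][1, 1] - 0.1), 1 / 255)
  expect_lt(abs(st[[2]][1, 1] - 0.5), 1 / 255)
  expect_lt(abs(st[[3]][1, 1] - 0.9), 1 / 255)
  # RGB slice is reduced by channel mean
  rgb <- array(c(matrix(1, 4, 4), matrix(0, 4, 4), matrix(0.5, 4, 4)),
               dim = c(4, 4, 3))
  dir2 <- tempfile(); dir.create(dir2)
  png::writePNG(rgb, file.path(dir2, "a1.png"))
  png::writePNG(matrix(0, 4, 4), file.path(dir2, "a2.png"))
  st2 <- readStack(dir2, axialStep = 3)
  expect_lt(abs(st2[[1]][1, 1] - 0.5), 1 / 255)
})

test_that("stack reading errors: empty, ragged, bad step", {
  dir <- tempfile(); dir.create(dir)
  expect_error(readStack(dir, axialStep = 3), "no slices")
  png::writePNG(matrix(0.2, 8, 8), file.path(dir, "a.png"))
  png::writePNG(matrix(0.2, 4, 4), file.path(dir, "b.png"))
  expect_error(readStack(dir, axialStep = 3), "ragged")
  expect_error(readStack(dir, axialStep = 0))
})

test_that("label files parse, merge stratum corneum, and reject bad rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("slice_index,label", "0,stratum_corneum", "1,Epidermis",
               "2,DEJ", "3,dermis"), path)
  expect_equal(strataLabels(readLabels(path)), c(0L, 0L, 1L, 2L))
  expect_error(readLabels(path, mergeSC = FALSE), "stratum_corneum")

  # TSV, no header, unsorted indices
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("2\tdermis", "0\tepidermis", "1\tDEJ"), path2)
  expect_equal(strataLabels(readLabels(path2)), c(0L, 1L, 2L))

  path3 <- tempfile(fileext = ".csv")
  writeLines(c("0,dermis"), path3)
  expect_equal(strataLabels(readLabels(path3)), 2L)

  path4 <- tempfile(fileext = ".csv")
  writeLines(c("0,basale"), path4)
  expect_error(readLabels(path4), "unknown stratum label")

  path5 <- tempfile(fileext = ".csv")
  writeLines(c("0,dermis", "0,DEJ"), path5)
  expect_error(readLabels(path5), "duplicate")
})

test_that("padAndMask clips, pads, masks, and preserves values", {
  f5 <- random_features(5, d = 4, seed = 1)
  f3 <- random_features(3, d = 4, seed = 2)
  pm <- padAndMask(list(f5, f3), maxLen = 5L)
  expect_equal(dim(pm$batch), c(2, 5, 4))
  expect_equal(pm$mask[1, ], rep(TRUE, 5))
  expect_equal(pm$mask[2, ], c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(pm$batch[2, 1:3, ], f3@features)      # values untouched
  expect_true(all(pm$batch[2, 4:5, ] == 0))
  # clipping keeps the first (shallowest) maxLen slices
  f101 <- random_features(101, d = 4, seed = 3)
  pm2 <- padAndMask(list(f101), maxLen = 71L)
  expect_equal(dim(pm2$batch)[2], 71)
  expect_true(all(pm2$mask))
  expect_equal(pm2$batch[1, , ], f101@features[1:71, ])
  expect_error(padAndMask(list()), "empty")
})

test_that("prediction tables validate and round-trip within 1e-9", {
  set.seed(9)
  n <- 50
  p <- matrix(stats::rexp(n * 3), n, 3)
  p <- p / rowSums(p)
  tab <- data.frame(
    stack_id = rep(c("a", "b"), each = 25),
    slice_index = rep(0:24, 2),
    depth_um = rep(seq(0, 72, by = 3), 2),
    p_epidermis = p[, 1], p_DEJ = p[, 2], p_dermis = p[, 3],
    argmax_label = max.col(p) - 1L,
    postprocessed_label = max.col(p) - 1L,
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  writePredictions(tab, path)
  expect_equal(length(readLines(path)), n + 1L)   # header + rows
  back <- readPredictions(path)
  for (col in names(tab)) {
    if (is.numeric(tab[[col]]))
      expect_true(all(abs(tab[[col]] - back[[col]]) < 1e-9))
    else expect_identical(tab[[col]], back[[col]])
  }
  bad <- tab
  bad$p_epidermis[1] <- bad$p_epidermis[1] - 0.2   # row sums to 0.8
  expect_error(writePredictions(bad, path), "sum to 1")
  bad2 <- tab[, c(2, 1, 3:8)]
  expect_error(validatePredictionTable(bad2), "columns")
  bad3 <- tab
  bad3$slice_index[2] <- 0L
  expect_error(validatePredictionTable(bad3), "increasing")
})
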