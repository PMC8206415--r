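.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic RCM dataset
#'
#' The simulator emulates the composition of clinical stack collections:
#' three ordered strata whose per-stack class fractions average 44%
#' epidermis, 34% DEJ and 22% dermis, stratum-specific textures (smooth
#' cellular blobs in the epidermis, fine anisotropic fibrous streaks in the
#' dermis, a linear mixture across the DEJ), multiplicative contrast decay
#' with depth below the epidermis, and additive sensor noise.
#'
#' @param nStacks number of stacks to simulate.
#' @param classFractions length-3 expected per-stack fractions of
#'   epidermis/DEJ/dermis slices; must be strictly positive and sum to 1.
#' @param subjects number of subjects; stacks are assigned round-robin and
#'   splits are stratified subject-wise so no subject spans two splits.
#' @param splitFractions train/validation/test fractions of subjects.
#' @param nSlicesRange inclusive range of slices per stack (clinical stacks
#'   run 20 to 101 slices; the desk-scale default draws 20-40).
#' @param imageSize height/width of each slice in pixels.
#' @param axialStepUm depth step between slices (um); 3 um matches the
#'   standard optical sectioning.
#' @param contrastDecayRate per-slice multiplicative decay rate applied below
#'   the first DEJ slice (models loss of contrast with depth).
#' @param noiseSigma standard deviation of additive Gaussian pixel noise.
#' @param boundaryJitter standard deviation of boundary placement around its
#'   expected depth, as a fraction of stack length.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return A validated list of class `SyntheticDatasetConfig`.
#' @export
syntheticDatasetConfig <- function(nStacks = 60L,
                                   classFractions = c(0.44, 0.34, 0.22),
                                   subjects = 20L,
                                   splitFractions = c(0.5, 0.15, 0.35),
                                   nSlicesRange = c(20L, 40L),
                                   imageSize = c(64L, 64L),
                                   axialStepUm = 3,
                                   contrastDecayRate = 0.03,
                                   noiseSigma = 0.04,
                                   boundaryJitter = 0.05,
                                   seed = 1L) {
  stopifnot(nStacks >= 1L, subjects >= 1L, nStacks >= subjects,
            length(classFractions) == 3L, length(splitFractions) == 3L,
            length(nSlicesRange) == 2L, nSlicesRange[1] >= 10L,
            nSlicesRange[2] <= 101L, nSlicesRange[1] <= nSlicesRange[2],
            axialStepUm > 0, contrastDecayRate >= 0, noiseSigma >= 0)
  if (any(classFractions <= 0) || any(classFractions >= 1) ||
      abs(sum(classFractions) - 1) > 1e-9)
    stop("classFractions must lie in (0,1) and sum to 1")
  if (any(splitFractions < 0) || abs(sum(splitFractions) - 1) > 1e-9)
    stop("splitFractions must be non-negative and sum to 1")
  if (splitFractions[1] <= 0)
    stop("the training fraction must be positive")
  structure(list(
    nStacks = as.integer(nStacks), classFractions = classFractions,
    subjects = as.integer(subjects), splitFractions = splitFractions,
    nSlicesRange = as.integer(nSlicesRange),
    imageSize = as.integer(imageSize), axialStepUm = axialStepUm,
    contrastDecayRate = contrastDecayRate, noiseSigma = noiseSigma,
    boundaryJitter = boundaryJitter, seed = as.integer(seed)
  ), class = "SyntheticDatasetConfig")
}

#' Draw the specification of one synthetic stack
#'
#' Boundary slice indices `b1` (first DEJ slice) and `b2` (first dermis
#' slice) are placed at the expected class-fraction depths plus Gaussian
#' jitter, then clipped so that `0 < b1 < b2 < nSlices` (indices 0-based).
#' Texture parameters are drawn from fixed stratum-typical ranges. Draws come
#' from the caller's RNG stream; the returned spec carries its own derived
#' seed so [generateStack()] is reproducible in isolation.
#'
#' @param config a [syntheticDatasetConfig()].
#' @param subjectId subject identifier stored in the spec.
#' @param stackId stack identifier.
#' @return A list of class `SyntheticStackSpec`.
#' @export
sampleStackSpec <- function(config, subjectId = "subject01",
                            stackId = "stack001") {
  n <- if (config$nSlicesRange[1] == config$nSlicesRange[2])
    config$nSlicesRange[1]
  else sample(config$nSlicesRange[1]:config$nSlicesRange[2], 1L)
  f <- config$classFractions
  if (round(n * f[1]) < 1 || round(n * f[2]) < 1 || round(n * f[3]) < 1)
    stop("class fraction targets force b1 >= b2 (or an empty stratum) at ",
         n, " slices")
  jit <- config$boundaryJitter * n
  b1 <- as.integer(round(n * f[1] + stats::rnorm(1, 0, jit)))
  b2 <- as.integer(round(n * (f[1] + f[2]) + stats::rnorm(1, 0, jit)))
  b1 <- max(1L, min(b1, n - 2L))
  b2 <- max(b1 + 1L, min(b2, n - 1L))
  structure(list(
    nSlices = n, imageSize = config$imageSize,
    axialStepUm = config$axialStepUm, depthOriginUm = 0,
    b1 = b1, b2 = b2,
    texture = list(
      epi_granularity = stats::runif(1, 2.5, 4.0),
      epi_contrast = stats::runif(1, 0.16, 0.24),
      derm_sigma_long = stats::runif(1, 3.0, 5.0),
      derm_sigma_short = stats::runif(1, 0.5, 0.9),
      derm_orientation = stats::runif(1, 0, pi),
      derm_contrast = stats::runif(1, 0.16, 0.24)
    ),
    contrastDecayRate = config$contrastDecayRate,
    noiseSigma = config$noiseSigma,
    seed = sample.int(.Machine$integer.max - 1L, 1L),
    subjectId = subjectId, stackId = stackId
  ), class = "SyntheticStackSpec")
}

# circular convolution of white noise with a (possibly anisotropic) Gaussian,
# standardized to zero mean / unit variance
.textured_field <- function(h, w, sigma_u, sigma_v, theta = 0) {
  yi <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1))
  xi <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1))
  Y <- matrix(yi, h, w)
  X <- matrix(xi, h, w, byrow = TRUE)
  U <- cos(theta) * X + sin(theta) * Y
  V <- -sin(theta) * X + cos(theta) * Y
  K <- exp(-0.5 * ((U / sigma_u)^2 + (V / sigma_v)^2))
  noise <- matrix(stats::rnorm(h * w), h, w)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(K), inverse = TRUE)) / (h * w)
  (f - mean(f)) / stats::sd(f)
}

.quantize16 <- function(m) round(pmin(pmax(m, 0), 1) * 65535) / 65535

#' Generate one synthetic RCM stack with known ground truth
#'
#' Slice `i` (0-based) is labeled epidermis if `i < b1`, DEJ if
#' `b1 <= i < b2`, dermis otherwise. Epidermal slices carry an isotropic
#' band-pass blob texture; dermal slices an anisotropic fibrous streak
#' texture; DEJ slices a linear mixture whose dermal weight ramps from 0 at
#' `b1` to 1 at `b2 - 1`. Every slice below the epidermis is scaled by
#' `exp(-contrastDecayRate * (i - b1))` before additive Gaussian noise.
#' Pixels are clamped to \[0, 1\] and quantized to the 16-bit grid so that a
#' TIFF write/read round-trip is lossless. Fully determined by `spec$seed`.
#'
#' @param spec a [sampleStackSpec()] result.
#' @return A list with `stack` ([RCMStack]), `labels`
#'   ([StrataLabelSequence]), and `boundaries` (the true [BoundaryEstimate]:
#'   depths `depthOrigin + b * axialStep` for `b` in `(b1, b2)`).
#' @export
generateStack <- function(spec) {
  stopifnot(inherits(spec, "SyntheticStackSpec"))
  n <- spec$nSlices; b1 <- spec$b1; b2 <- spec$b2
  stopifnot(0 < b1, b1 < b2, b2 < n)
  h <- spec$imageSize[1]; w <- spec$imageSize[2]
  tx <- spec$texture
  slices <- .with_seed(spec$seed, {
    lapply(0:(n - 1), function(i) {
      epi <- .textured_field(h, w, tx$epi_granularity, tx$epi_granularity)
      base <- if (i < b1) {
        tx$epi_contrast * epi
      } else {
        derm <- .textured_field(h, w, tx$derm_sigma_long, tx$derm_sigma_short,
                                tx$derm_orientation)
        if (i < b2) {
          mixw <- (i - b1) / max(1L, b2 - 1L - b1)
          (1 - mixw) * tx$epi_contrast * epi + mixw * tx$derm_contrast * derm
        } else {
          tx$derm_contrast * derm
        }
      }
      decay <- if (i >= b1) exp(-spec$contrastDecayRate * (i - b1)) else 1
      img <- decay * (0.5 + base) +
        matrix(stats::rnorm(h * w, 0, spec$noiseSigma), h, w)
      .quantize16(img)
    })
  })
  labels <- ifelse(0:(n - 1) < b1, 0L, ifelse(0:(n - 1) < b2, 1L, 2L))
  list(
    stack = RCMStack(slices, axialStep = spec$axialStepUm,
                     depthOrigin = spec$depthOriginUm,
                     stackId = spec$stackId, subjectId = spec$subjectId),
    labels = StrataLabelSequence(labels, stackId = spec$stackId),
    boundaries = BoundaryEstimate(
      epiDejUm = spec$depthOriginUm + b1 * spec$axialStepUm,
      dejDermUm = spec$depthOriginUm + b2 * spec$axialStepUm,
      stackId = spec$stackId)
  )
}

#' Ground-truth labels and boundaries of a spec without rendering images
#'
#' @param spec a [sampleStackSpec()] result.
#' @return As [generateStack()] but with `stack = NULL`; used where only the
#'   label geometry matters (e.g. post-processing experiments).
#' @export
specLabels <- function(spec) {
  i <- 0:(spec$nSlices - 1)
  labels <- ifelse(i < spec$b1, 0L, ifelse(i < spec$b2, 1L, 2L))
  list(
    stack = NULL,
    labels = StrataLabelSequence(labels, stackId = spec$stackId),
    boundaries = BoundaryEstimate(
      epiDejUm = spec$depthOriginUm + spec$b1 * spec$axialStepUm,
      dejDermUm = spec$depthOriginUm + spec$b2 * spec$axialStepUm,
      stackId = spec$stackId)
  )
}

#' Generate a seeded synthetic dataset with a subject-wise split
#'
#' Stacks are assigned to subjects round-robin; subjects are shuffled and
#' partitioned into train/validation/test so that no subject appears in two
#' splits and split sizes match the requested fractions within rounding.
#'
#' @param config a [syntheticDatasetConfig()].
#' @param render generate slice images (`TRUE`) or only labels/boundaries.
#' @return A list with `stacks` (list of [generateStack()]/[specLabels()]
#'   results), `specs`, and `manifest` (a data.frame with stack_id,
#'   subject_id, split, b1, b2, n_slices, axial_step_um, depth_origin_um,
#'   epi_dej_um, dej_derm_um).
#' @export
generateDataset <- function(config, render = TRUE) {
  stopifnot(inherits(config, "SyntheticDatasetConfig"))
  .with_seed(config$seed, {
    subj <- sprintf("subject%02d", seq_len(config$subjects))
    assignment <- sample(rep_len(subj, config$nStacks))
    counts <- floor(config$subjects * config$splitFractions)
    rem <- config$subjects - sum(counts)
    if (rem > 0) {
      extra <- order(config$subjects * config$splitFractions - counts,
                     decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    if (config$subjects < 3L)
      warning("fewer subjects than splits: some splits will be empty")
    split_of <- rep(c("train", "val", "test"), counts)
    names(split_of) <- sample(subj)
    specs <- lapply(seq_len(config$nStacks), function(k) {
      sampleStackSpec(config, subjectId = assignment[k],
                      stackId = sprintf("stack%03d", k))
    })
    stacks <- lapply(specs, if (render) generateStack else specLabels)
    manifest <- data.frame(
      stack_id = vapply(specs, `[[`, character(1), "stackId"),
      subject_id = vapply(specs, `[[`, character(1), "subjectId"),
      split = unname(split_of[assignment]),
      b1 = vapply(specs, `[[`, integer(1), "b1"),
      b2 = vapply(specs, `[[`, integer(1), "b2"),
      n_slices = vapply(specs, `[[`, integer(1), "nSlices"),
      axial_step_um = config$axialStepUm,
      depth_origin_um = 0,
      stringsAsFactors = FALSE
    )
    manifest$epi_dej_um <- manifest$depth_origin_um +
      manifest$b1 * manifest$axial_step_um
    manifest$dej_derm_um <- manifest$depth_origin_um +
      manifest$b2 * manifest$axial_step_um
    list(stacks = stacks, specs = specs, manifest = manifest)
  })
}

#' Flip labels near strata boundaries
#'
#' Emulates the dominant error mode of slice classifiers: slices acquired
#' near a boundary contain features of both strata and get swapped to the
#' adjacent class. Each slice within `window` slices of a true boundary is
#' independently flipped with probability `flipProb` to the class on the
#' other side of its nearest boundary; slices far from boundaries are never
#' touched. Draws come from the caller's RNG stream.
#'
#' @param labels a [StrataLabelSequence] or integer vector.
#' @param flipProb flip probability in \[0, 1\].
#' @param window eligibility half-width in slices: for a boundary at index
#'   `b` (first slice of the deeper stratum, 0-based), slices
#'   `b - window .. b + window - 1` are eligible.
#' @return Corrupted labels of the same type as the input.
#' @export
corruptLabels <- function(labels, flipProb, window = 1L) {
  stopifnot(flipProb >= 0, flipProb <= 1, window >= 0)
  x <- .as_labels(labels)
  n <- length(x)
  changes <- which(diff(x) != 0)        # boundary at 0-based index = changes
  out <- x
  for (b in changes) {                  # b: 1-based index of last shallower slice
    lo <- max(1L, b - window + 1L)
    hi <- min(n, b + window)
    for (i in lo:hi) {
      if (stats::runif(1) < flipProb) {
        out[i] <- if (i <= b) x[b + 1L] else x[b]
      }
    }
  }
  .wrap_labels(out, labels)
}
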