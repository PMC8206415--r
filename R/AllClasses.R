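#' @useDynLib rcmstrata, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' RCMStack: a depth-ordered stack of reflectance confocal microscopy slices
#'
#' The unit of inference: an ordered set of single-channel en-face images
#' acquired at one lateral skin position over consecutive depths. Slices are
#' stored shallow-to-deep as numeric matrices with values in \[0, 1\]; the
#' physical depth of slice `i` (1-based) is
#' `depthOrigin(x) + (i - 1) * axialStep(x)` micrometers.
#'
#' @slot slices list of numeric matrices, all with identical dimensions.
#' @slot axialStep positive numeric, depth between consecutive slices (um).
#' @slot depthOrigin numeric, depth of the first slice (um).
#' @slot stackId character identifier.
#' @slot subjectId character identifier of the imaged subject.
#'
#' @aliases RCMStack
#' @exportClass RCMStack
setClass("RCMStack",
  representation(
    slices = "list",
    axialStep = "numeric",
    depthOrigin = "numeric",
    stackId = "character",
    subjectId = "character"
  ),
  prototype(axialStep = 3, depthOrigin = 0, stackId = "stack", subjectId = "subject")
)

setValidity("RCMStack", function(object) {
  msg <- character()
  if (length(object@slices) < 2L)
    msg <- c(msg, "an RCM stack must contain at least 2 slices")
  if (!all(vapply(object@slices, is.matrix, logical(1))))
    msg <- c(msg, "all slices must be numeric matrices")
  else {
    dims <- vapply(object@slices, dim, integer(2))
    if (length(object@slices) && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
      msg <- c(msg, "ragged stack: all slices must share identical dimensions")
  }
  if (length(object@axialStep) != 1L || !is.finite(object@axialStep) ||
      object@axialStep <= 0)
    msg <- c(msg, "axialStep must be a single positive number (um)")
  if (length(object@depthOrigin) != 1L || !is.finite(object@depthOrigin))
    msg <- c(msg, "depthOrigin must be a single finite number (um)")
  if (length(msg)) msg else TRUE
})

#' StrataLabelSequence: per-slice ordinal skin-stratum labels
#'
#' Integer codes follow the fixed anatomical depth order
#' epidermis (0) < DEJ (1) < dermis (2). Stratum corneum, when present in a
#' label file, is merged into the epidermis class on ingest.
#'
#' @slot labels integer vector with values in {0, 1, 2}.
#' @slot stackId character identifier of the paired stack.
#'
#' @aliases StrataLabelSequence
#' @exportClass StrataLabelSequence
setClass("StrataLabelSequence",
  representation(labels = "integer", stackId = "character"),
  prototype(stackId = "stack")
)

setValidity("StrataLabelSequence", function(object) {
  if (length(object@labels) &&
      (anyNA(object@labels) || !all(object@labels %in% 0:2)))
    return("labels must all be in {0 (epidermis), 1 (DEJ), 2 (dermis)}")
  TRUE
})

#' FeatureSequence: per-slice embedding vectors from the frozen slice encoder
#'
#' One row per slice, in shallow-to-deep order; columns are the dimensions of
#' the encoder's penultimate (linear) layer.
#'
#' @slot features numeric matrix, slices x embedding dimensions.
#' @slot stackId character identifier of the source stack.
#'
#' @aliases FeatureSequence
#' @exportClass FeatureSequence
setClass("FeatureSequence",
  representation(features = "matrix", stackId = "character"),
  prototype(stackId = "stack")
)

setValidity("FeatureSequence", function(object) {
  if (!is.numeric(object@features))
    return("features must be a numeric matrix")
  if (length(object@features) && !all(is.finite(object@features)))
    return("features must be finite")
  TRUE
})

#' SliceEncoder: a convolutional classifier over single RCM slices
#'
#' Built by [buildEncoder()], trained with [trainEncoder()] and then used as a
#' frozen per-slice feature extractor ([extractFeatures()]). The embedding is
#' the penultimate fully connected layer taken before its non-linearity.
#'
#' @slot config list of architecture/augmentation/optimizer settings
#'   (see [encoderConfig()]).
#' @slot params list of weight matrices/vectors.
#' @slot trained logical flag.
#'
#' @aliases SliceEncoder
#' @exportClass SliceEncoder
setClass("SliceEncoder",
  representation(config = "list", params = "list", trained = "logical"),
  prototype(trained = FALSE)
)

#' RCNModel: recurrent network over frozen slice-feature sequences
#'
#' A bidirectional GRU encoder producing one encoding per slice, an attention
#' stage (identity, Toeplitz convex-kernel, or global additive), and an
#' autoregressive decoder emitting per-slice class probabilities.
#'
#' @slot config list of hyperparameters (see [rcnConfig()]).
#' @slot params list of weight matrices/vectors.
#' @slot trained logical flag.
#'
#' @aliases RCNModel
#' @exportClass RCNModel
setClass("RCNModel",
  representation(config = "list", params = "list", trained = "logical"),
  prototype(trained = FALSE)
)

#' BoundaryEstimate: strata boundary depths for one stack
#'
#' Depths are in micrometers from the stack's depth origin. A boundary whose
#' deeper stratum never appears in the label sequence is `NA` (absent) and is
#' excluded pairwise from error summaries.
#'
#' @slot epiDejUm numeric, depth of the epidermis-DEJ boundary (um) or NA.
#' @slot dejDermUm numeric, depth of the DEJ-dermis boundary (um) or NA.
#' @slot stackId character identifier.
#'
#' @aliases BoundaryEstimate
#' @exportClass BoundaryEstimate
setClass("BoundaryEstimate",
  representation(epiDejUm = "numeric", dejDermUm = "numeric", stackId = "character"),
  prototype(epiDejUm = NA_real_, dejDermUm = NA_real_, stackId = "stack")
)

setValidity("BoundaryEstimate", function(object) {
  if (length(object@epiDejUm) != 1L || length(object@dejDermUm) != 1L)
    return("boundary depths must be single values (possibly NA)")
  if (!is.na(object@epiDejUm) && !is.na(object@dejDermUm) &&
      object@epiDejUm > object@dejDermUm)
    return("epidermis-DEJ boundary cannot lie below the DEJ-dermis boundary")
  TRUE
})
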