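#' @name rcmstrata-accessors
#' @title Accessors for rcmstrata S4 classes
#' @description Small accessor generics for the package's data containers.
#' @param x an object of the documented class.
#' @return The slot value (see each method).
NULL

#' @rdname rcmstrata-accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname rcmstrata-accessors
#' @export
setGeneric("axialStep", function(x) standardGeneric("axialStep"))

#' @rdname rcmstrata-accessors
#' @export
setGeneric("depthOrigin", function(x) standardGeneric("depthOrigin"))

#' @rdname rcmstrata-accessors
#' @export
setGeneric("stackId", function(x) standardGeneric("stackId"))

#' @rdname rcmstrata-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname rcmstrata-accessors
#' @export
setGeneric("strataLabels", function(x) standardGeneric("strataLabels"))

#' @rdname rcmstrata-accessors
#' @export
setGeneric("sliceDepths", function(x) standardGeneric("sliceDepths"))

#' @rdname rcmstrata-accessors
#' @export
setMethod("nSlices", "RCMStack", function(x) length(x@slices))

#' @rdname rcmstrata-accessors
#' @export
setMethod("axialStep", "RCMStack", function(x) x@axialStep)

#' @rdname rcmstrata-accessors
#' @export
setMethod("depthOrigin", "RCMStack", function(x) x@depthOrigin)

#' @rdname rcmstrata-accessors
#' @export
setMethod("stackId", "RCMStack", function(x) x@stackId)

#' @rdname rcmstrata-accessors
#' @export
setMethod("subjectId", "RCMStack", function(x) x@subjectId)

#' @rdname rcmstrata-accessors
#' @export
setMethod("sliceDepths", "RCMStack", function(x)
  x@depthOrigin + (seq_len(nSlices(x)) - 1) * x@axialStep)

#' @rdname rcmstrata-accessors
#' @export
setMethod("stackId", "StrataLabelSequence", function(x) x@stackId)

#' @rdname rcmstrata-accessors
#' @export
setMethod("strataLabels", "StrataLabelSequence", function(x) x@labels)

#' @rdname rcmstrata-accessors
#' @export
setMethod("stackId", "FeatureSequence", function(x) x@stackId)

#' Extract a slice from an RCMStack
#'
#' @param x an [RCMStack].
#' @param i integer slice index (1-based, shallow to deep).
#' @param j,...,drop ignored.
#' @return The slice as a numeric matrix.
#' @export
setMethod("[[", "RCMStack", function(x, i, j, ...) x@slices[[i]])

setMethod("show", "RCMStack", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf(
    "RCMStack '%s' (subject '%s'): %d slices of %dx%d px, step %.2f um, origin %.2f um\n",
    object@stackId, object@subjectId, nSlices(object), d[1], d[2],
    object@axialStep, object@depthOrigin))
})

setMethod("show", "StrataLabelSequence", function(object) {
  cat(sprintf("StrataLabelSequence '%s' (%d slices): %s\n",
              object@stackId, length(object@labels),
              paste(object@labels, collapse = "")))
})

setMethod("show", "FeatureSequence", function(object) {
  cat(sprintf("FeatureSequence '%s': %d slices x %d dims\n",
              object@stackId, nrow(object@features), ncol(object@features)))
})

setMethod("show", "SliceEncoder", function(object) {
  cat(sprintf("SliceEncoder (%s, embedding %d-d, %s)\n",
              object@config$backbone, object@config$embedding_dim,
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "RCNModel", function(object) {
  extra <- switch(object@config$variant,
    toeplitz = sprintf(", D=%d", object@config$D),
    partial_seq = sprintf(", neighborhood=%d", object@config$neighborhood),
    "")
  cat(sprintf("RCNModel (%s%s, GRU %d/dir%s, %s)\n",
              object@config$variant, extra, object@config$gru_hidden,
              if (object@config$bidirectional) " bidirectional" else "",
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "BoundaryEstimate", function(object) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.2f um", v)
  cat(sprintf("BoundaryEstimate '%s': epidermis-DEJ %s, DEJ-dermis %s\n",
              object@stackId, fmt(object@epiDejUm), fmt(object@dejDermUm)))
})

#' Construct a StrataLabelSequence
#'
#' @param labels integer vector with values in {0, 1, 2}
#'   (0 = epidermis, 1 = DEJ, 2 = dermis).
#' @param stackId character identifier of the paired stack.
#' @return A [StrataLabelSequence].
#' @export
StrataLabelSequence <- function(labels, stackId = "stack") {
  new("StrataLabelSequence", labels = as.integer(labels), stackId = stackId)
}

#' Construct a FeatureSequence
#'
#' @param features numeric matrix, one row per slice.
#' @param stackId character identifier of the source stack.
#' @return A [FeatureSequence].
#' @export
FeatureSequence <- function(features, stackId = "stack") {
  new("FeatureSequence", features = as.matrix(features), stackId = stackId)
}

#' Construct an RCMStack
#'
#' @param slices list of numeric matrices (identical dimensions), ordered
#'   shallow to deep, pixel values in \[0, 1\].
#' @param axialStep positive depth step between consecutive slices (um).
#' @param depthOrigin depth of the first slice (um).
#' @param stackId,subjectId character identifiers.
#' @return An [RCMStack].
#' @export
RCMStack <- function(slices, axialStep, depthOrigin = 0,
                     stackId = "stack", subjectId = "subject") {
  new("RCMStack", slices = slices, axialStep = axialStep,
      depthOrigin = depthOrigin, stackId = stackId, subjectId = subjectId)
}

#' Construct a BoundaryEstimate
#'
#' @param epiDejUm depth (um) of the epidermis-DEJ boundary, or NA if the DEJ
#'   never appears.
#' @param dejDermUm depth (um) of the DEJ-dermis boundary, or NA if the dermis
#'   never appears.
#' @param stackId character identifier.
#' @return A [BoundaryEstimate].
#' @export
BoundaryEstimate <- function(epiDejUm = NA_real_, dejDermUm = NA_real_,
                             stackId = "stack") {
  new("BoundaryEstimate", epiDejUm = as.numeric(epiDejUm),
      dejDermUm = as.numeric(dejDermUm), stackId = stackId)
}
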