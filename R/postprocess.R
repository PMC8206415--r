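.as_labels <- function(x) {
  if (is(x, "StrataLabelSequence")) x@labels else as.integer(x)
}

.wrap_labels <- function(values, template) {
  if (is(template, "StrataLabelSequence"))
    StrataLabelSequence(values, stackId = template@stackId)
  else as.integer(values)
}

#' 3-slice median filter over an ordinal label sequence
#'
#' Replaces each label by the median of the ordinal codes in its 3-slice
#' window, removing isolated outlier classifications. Edges are handled by
#' replicating the terminal labels, which leaves the first and last labels
#' unchanged and keeps constant sequences fixed.
#'
#' @param labels a [StrataLabelSequence] or integer vector of codes in
#'   {0, 1, 2}.
#' @return Filtered labels of the same type and length as the input.
#' @export
#' @examples
#' medianFilter3(c(0, 0, 1, 0, 1, 1, 2, 2))
medianFilter3 <- function(labels) {
  x <- .as_labels(labels)
  if (length(x) >= 3L) {
    # replicate-edge 3-median == runmed(k = 3, endrule = "keep")
    x <- as.integer(stats::runmed(x, 3L, endrule = "keep"))
  }
  .wrap_labels(x, labels)
}

#' Causal max filter: inclusive prefix maximum of ordinal labels
#'
#' Replaces each prediction with the maximum over the predictions up to and
#' including it, so the output is monotone non-decreasing in depth and
#' therefore free of anatomically impossible transitions. The filter is
#' idempotent and leaves already-monotone sequences unchanged.
#'
#' @inheritParams medianFilter3
#' @return Filtered labels of the same type and length as the input.
#' @export
#' @examples
#' causalMax(c(0, 1, 0, 2, 1, 2))
causalMax <- function(labels) {
  .wrap_labels(cummax(.as_labels(labels)), labels)
}

#' Enforce anatomical consistency on a predicted label sequence
#'
#' The two-step heuristic applied to raw per-slice predictions: a 3-slice
#' median filter to remove outlier classifications, followed by a causal max
#' filter. The median step matters: it deletes isolated too-deep outliers
#' (e.g. a single early DEJ call) before the running maximum would lock them
#' in. The output is always monotone non-decreasing, so it contains none of
#' the three ordering-violating transitions (see [countInconsistencies()]).
#' A monotone epidermis-to-dermis skip can still survive when two or more
#' consecutive dermis outliers defeat the 3-slice median; the heuristic
#' operates in the label domain only and cannot invent the missing DEJ.
#'
#' @inheritParams medianFilter3
#' @return Consistent (monotone non-decreasing) labels.
#' @export
enforceConsistency <- function(labels) {
  causalMax(medianFilter3(labels))
}

#' Extract strata boundary depths from a consistent label sequence
#'
#' The boundary depth is the depth of the first slice of the deeper stratum:
#' the epidermis-DEJ boundary at the first slice labeled DEJ or deeper, the
#' DEJ-dermis boundary at the first slice labeled dermis. A boundary whose
#' deeper stratum never occurs is reported absent (`NA`). Depth of slice `i`
#' (0-based) is `depthOriginUm + i * axialStepUm`.
#'
#' @param labels a monotone non-decreasing [StrataLabelSequence] or integer
#'   vector; run [enforceConsistency()] first.
#' @param axialStepUm positive depth step (um).
#' @param depthOriginUm depth of slice 0 (um).
#' @return A [BoundaryEstimate].
#' @export
#' @examples
#' extractBoundaries(c(0, 0, 0, 1, 1, 2, 2), axialStepUm = 3)
extractBoundaries <- function(labels, axialStepUm, depthOriginUm = 0) {
  stopifnot(axialStepUm > 0)
  x <- .as_labels(labels)
  if (is.unsorted(x))
    stop("labels are not monotone: enforce consistency first")
  depth <- function(i)
    if (length(i)) depthOriginUm + (i[1] - 1) * axialStepUm else NA_real_
  BoundaryEstimate(
    epiDejUm = depth(which(x >= 1L)),
    dejDermUm = depth(which(x == 2L)),
    stackId = if (is(labels, "StrataLabelSequence")) labels@stackId else "stack")
}
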