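.INCONSISTENT_PAIRS <- data.frame(
  from = c(0L, 1L, 2L, 2L),
  to = c(2L, 0L, 0L, 1L),
  name = c("epi_to_derm", "dej_to_epi", "derm_to_epi", "derm_to_dej")
)

#' Count anatomically inconsistent transitions in a label sequence
#'
#' Skin strata keep a strict depth order, so moving down a stack the only
#' legal transitions are within-stratum or one step deeper. Each adjacent
#' slice pair violating that order is counted, split into the four impossible
#' transition types: epidermis to dermis (a skipped DEJ), DEJ to epidermis,
#' dermis to epidermis, and dermis to DEJ.
#'
#' @param labels a [StrataLabelSequence] or integer vector of codes in
#'   {0, 1, 2}.
#' @return A list with counts `epi_to_derm`, `dej_to_epi`, `derm_to_epi`,
#'   `derm_to_dej` and their `total`.
#' @export
#' @examples
#' countInconsistencies(c(0, 2, 1, 0))
countInconsistencies <- function(labels) {
  x <- .as_labels(labels)
  from <- x[-length(x)]
  to <- x[-1]
  counts <- mapply(function(f, t) sum(from == f & to == t),
                   .INCONSISTENT_PAIRS$from, .INCONSISTENT_PAIRS$to)
  names(counts) <- .INCONSISTENT_PAIRS$name
  c(as.list(counts), list(total = sum(counts)))
}

#' Slice-classification report: accuracy, per-class sensitivity/specificity
#'
#' Computes the 3x3 confusion matrix over aligned slices and, per class in
#' one-vs-rest form, sensitivity `TP / (TP + FN)` and specificity
#' `TN / (TN + FP)`. A class absent from the truth has undefined (NaN)
#' sensitivity and is excluded from any macro summary the caller forms.
#'
#' @param truth,pred [StrataLabelSequence] objects, integer vectors, or lists
#'   of either; flattened in order and compared slice-wise.
#' @return A list with `accuracy`, named numeric vectors `sensitivity` and
#'   `specificity` (classes epidermis/DEJ/dermis), and the `confusion` matrix
#'   (rows = truth, columns = predicted).
#' @export
classificationReport <- function(truth, pred) {
  flatten <- function(x) {
    if (is.list(x)) unlist(lapply(x, .as_labels)) else .as_labels(x)
  }
  t <- flatten(truth)
  p <- flatten(pred)
  if (length(t) != length(p))
    stop("truth and prediction lengths differ (", length(t), " vs ",
         length(p), ")")
  cls <- c("epidermis", "DEJ", "dermis")
  confusion <- table(factor(t, levels = 0:2), factor(p, levels = 0:2))
  confusion <- matrix(as.integer(confusion), 3, 3,
                      dimnames = list(truth = cls, predicted = cls))
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- sum(confusion) - tp - fn - fp
  list(
    accuracy = sum(tp) / sum(confusion),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    confusion = confusion
  )
}

#' Boundary localization error in micrometers
#'
#' Mean absolute error between estimated and true strata boundary depths,
#' computed separately for the epidermis-DEJ and DEJ-dermis boundaries over
#' stacks matched by `stackId`. Pairs where either side is absent are
#' excluded from that boundary's mean and counted in `excluded`; signed
#' errors (estimate minus truth) are returned per stack for histogramming.
#'
#' @param estimates,truths lists of [BoundaryEstimate] objects; matched by
#'   `stackId`.
#' @return A list with `mae_epi_dej_um`, `mae_dej_derm_um`, `excluded`
#'   (counts per boundary), and a data.frame `errors` of per-stack signed
#'   errors.
#' @export
boundaryMAE <- function(estimates, truths) {
  ids_e <- vapply(estimates, function(b) b@stackId, character(1))
  ids_t <- vapply(truths, function(b) b@stackId, character(1))
  common <- intersect(ids_e, ids_t)
  if (length(common) == 0L) stop("no overlapping stack_ids")
  get <- function(lst, ids, slot_) {
    vapply(common, function(id) slot(lst[[match(id, ids)]], slot_), numeric(1))
  }
  err_ed <- get(estimates, ids_e, "epiDejUm") - get(truths, ids_t, "epiDejUm")
  err_dd <- get(estimates, ids_e, "dejDermUm") - get(truths, ids_t, "dejDermUm")
  list(
    mae_epi_dej_um = mean(abs(err_ed), na.rm = TRUE),
    mae_dej_derm_um = mean(abs(err_dd), na.rm = TRUE),
    excluded = c(epi_dej = sum(is.na(err_ed)), dej_derm = sum(is.na(err_dd))),
    errors = data.frame(stack_id = common, epi_dej_um = unname(err_ed),
                        dej_derm_um = unname(err_dd), row.names = NULL)
  )
}

#' Evaluate a prediction run against ground truth
#'
#' Reproduces the three evaluation surfaces: slice classification on the raw
#' argmax labels, inconsistent-transition counts on both raw and
#' post-processed labels (consistency is a property of the model's raw
#' output; post-processing trivially zeroes it), and boundary mean absolute
#' error on the post-processed labels against manifest truth.
#'
#' @param predictions a prediction table (see [validatePredictionTable()]).
#' @param truthLabels named list of [StrataLabelSequence] keyed by stack id.
#' @param manifest data.frame with columns `stack_id`, `axial_step_um`,
#'   `depth_origin_um`, `epi_dej_um`, `dej_derm_um` (true boundary depths).
#' @param path optional file; when given the report is serialized as JSON.
#' @return A list with `classification`, `consistency_raw`,
#'   `consistency_post`, `boundaries`, and `missing_stacks` (stacks in the
#'   manifest without predictions; evaluation continues without them).
#' @export
evaluateRun <- function(predictions, truthLabels, manifest, path = NULL) {
  validatePredictionTable(predictions)
  pred_ids <- unique(predictions$stack_id)
  missing <- setdiff(manifest$stack_id, pred_ids)
  if (length(missing))
    warning("no predictions for stacks: ", paste(missing, collapse = ", "))
  ids <- intersect(manifest$stack_id, pred_ids)
  ids <- intersect(ids, names(truthLabels))
  if (length(ids) == 0L) stop("empty evaluation: no stacks with predictions")

  raw <- post <- truth <- vector("list", length(ids))
  est_b <- true_b <- vector("list", length(ids))
  cons_raw <- cons_post <- 0L
  for (k in seq_along(ids)) {
    id <- ids[k]
    rows <- predictions[predictions$stack_id == id, , drop = FALSE]
    raw[[k]] <- as.integer(rows$argmax_label)
    post[[k]] <- as.integer(rows$postprocessed_label)
    truth[[k]] <- truthLabels[[id]]
    cons_raw <- cons_raw + countInconsistencies(raw[[k]])$total
    cons_post <- cons_post + countInconsistencies(post[[k]])$total
    mrow <- manifest[manifest$stack_id == id, , drop = FALSE][1, ]
    est_b[[k]] <- extractBoundaries(post[[k]], mrow$axial_step_um,
                                    mrow$depth_origin_um)
    est_b[[k]]@stackId <- id
    true_b[[k]] <- BoundaryEstimate(mrow$epi_dej_um, mrow$dej_derm_um,
                                    stackId = id)
  }
  report <- list(
    classification = classificationReport(truth, raw),
    consistency_raw = cons_raw,
    consistency_post = cons_post,
    boundaries = boundaryMAE(est_b, true_b),
    missing_stacks = missing,
    n_stacks = length(ids)
  )
  if (!is.null(path)) {
    out <- report
    out$classification$confusion <- as.data.frame.matrix(
      out$classification$confusion)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  report
}
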