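.LABEL_NAMES <- c("epidermis", "DEJ", "dermis")

#' Build a per-slice prediction table for one stack
#'
#' @param stack an [RCMStack] (supplies depths and ids); slice_index is
#'   0-based.
#' @param probs slices x 3 row-stochastic probability matrix.
#' @param postprocessed integer vector of consistency-enforced labels.
#' @return A data.frame in the standard prediction schema (see
#'   [validatePredictionTable()]).
#' @export
makePredictionTable <- function(stack, probs, postprocessed) {
  n <- nrow(probs)
  argmax <- max.col(probs, ties.method = "first") - 1L
  tab <- data.frame(
    stack_id = stackId(stack),
    slice_index = 0:(n - 1L),
    depth_um = sliceDepths(stack)[seq_len(n)],
    p_epidermis = probs[, 1], p_DEJ = probs[, 2], p_dermis = probs[, 3],
    argmax_label = argmax,
    postprocessed_label = as.integer(postprocessed),
    stringsAsFactors = FALSE
  )
  validatePredictionTable(tab)
}

#' Predict strata labels for whole stacks
#'
#' Runs the frozen encoder, the sequence model, and the consistency
#' heuristic over each stack and returns one combined prediction table.
#' Deterministic: repeated calls give identical output.
#'
#' @param encoder a trained [SliceEncoder].
#' @param model a trained [RCNModel].
#' @param stacks a list of [RCMStack] objects (or a single one).
#' @return A prediction table covering all stacks.
#' @export
predictStacks <- function(encoder, model, stacks) {
  if (is(stacks, "RCMStack")) stacks <- list(stacks)
  tabs <- lapply(stacks, function(st) {
    feats <- extractFeatures(encoder, st)
    res <- predictRCN(model, feats)
    post <- enforceConsistency(res$labels[seq_len(res$length)])
    makePredictionTable(st, res$probs[seq_len(res$length), , drop = FALSE],
                        post)
  })
  do.call(rbind, tabs)
}

.write_labels_csv <- function(labels, path) {
  df <- data.frame(slice_index = seq_along(labels@labels) - 1L,
                   label = .LABEL_NAMES[labels@labels + 1L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes one multi-page 16-bit TIFF and one labels CSV per stack, plus a
#' manifest CSV with the subject-wise split and true boundary depths. Logs
#' per-split stack counts.
#'
#' @param config a [syntheticDatasetConfig()].
#' @param outputDir output directory (created if needed).
#' @param force overwrite an existing non-empty directory.
#' @return The manifest data.frame, invisibly.
#' @export
cmdSimulate <- function(config, outputDir, force = FALSE) {
  if (dir.exists(outputDir) && length(list.files(outputDir)) > 0 && !force)
    stop("output directory ", outputDir, " is not empty (use force = TRUE)")
  dir.create(file.path(outputDir, "stacks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outputDir, "labels"), showWarnings = FALSE)
  ds <- generateDataset(config, render = TRUE)
  for (k in seq_along(ds$stacks)) {
    id <- ds$manifest$stack_id[k]
    writeStack(ds$stacks[[k]]$stack,
               file.path(outputDir, "stacks", paste0(id, ".tiff")))
    .write_labels_csv(ds$stacks[[k]]$labels,
                      file.path(outputDir, "labels", paste0(id, ".csv")))
  }
  utils::write.csv(ds$manifest, file.path(outputDir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  counts <- table(ds$manifest$split)
  message("simulated ", nrow(ds$manifest), " stacks (",
          paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  invisible(ds$manifest)
}

.load_dataset_dir <- function(dataDir) {
  manifest <- utils::read.csv(file.path(dataDir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  stacks <- list(); labels <- list()
  for (k in seq_len(nrow(manifest))) {
    id <- manifest$stack_id[k]
    stacks[[id]] <- readStack(
      file.path(dataDir, "stacks", paste0(id, ".tiff")),
      axialStep = manifest$axial_step_um[k],
      depthOrigin = manifest$depth_origin_um[k],
      stackId = id, subjectId = manifest$subject_id[k])
    labels[[id]] <- readLabels(file.path(dataDir, "labels",
                                         paste0(id, ".csv")), stackId = id)
  }
  list(manifest = manifest, stacks = stacks, labels = labels)
}

.split_slices <- function(ds, split) {
  ids <- ds$manifest$stack_id[ds$manifest$split == split]
  imgs <- list(); labs <- integer()
  for (id in ids) {
    imgs <- c(imgs, ds$stacks[[id]]@slices)
    labs <- c(labs, ds$labels[[id]]@labels)
  }
  list(images = imgs, labels = labs, ids = ids)
}

#' Train pipeline stages from a simulated dataset directory
#'
#' Stage `"encoder"` trains the slice CNN on individual training-split
#' slices. Stage `"rcn"` requires an existing encoder checkpoint, extracts
#' frozen features for every stack, and trains the sequence model. Each
#' stage saves a best-validation checkpoint plus a history CSV.
#'
#' @param dataDir dataset directory written by [cmdSimulate()].
#' @param outputDir checkpoint/history directory.
#' @param stage `"encoder"` or `"rcn"`.
#' @param encoderCfg an [encoderConfig()] (encoder stage).
#' @param rcnCfg an [rcnConfig()] (rcn stage).
#' @return The training history data.frame, invisibly.
#' @export
cmdTrain <- function(dataDir, outputDir, stage = c("encoder", "rcn"),
                     encoderCfg = encoderConfig(), rcnCfg = rcnConfig()) {
  stage <- match.arg(stage)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  ds <- .load_dataset_dir(dataDir)
  if (stage == "encoder") {
    tr <- .split_slices(ds, "train")
    va <- .split_slices(ds, "val")
    enc <- buildEncoder(encoderCfg)
    fit <- trainEncoder(enc, tr$images, tr$labels, va$images, va$labels)
    saveCheckpoint(fit$encoder, file.path(outputDir, "encoder.rds"))
    utils::write.csv(fit$history, file.path(outputDir, "encoder_history.csv"),
                     row.names = FALSE)
    message("encoder: best validation accuracy ",
            sprintf("%.3f", max(fit$history$val_accuracy)))
    return(invisible(fit$history))
  }
  encPath <- file.path(outputDir, "encoder.rds")
  if (!file.exists(encPath))
    stop("missing encoder checkpoint ", encPath,
         ": train stage 'encoder' first")
  encoder <- loadCheckpoint(encPath)
  feats <- lapply(ds$stacks, function(st) extractFeatures(encoder, st))
  pick <- function(split) ds$manifest$stack_id[ds$manifest$split == split]
  fit <- trainRCN(buildRCN(rcnCfg),
                  feats[pick("train")], ds$labels[pick("train")],
                  feats[pick("val")], ds$labels[pick("val")])
  tag <- if (rcnCfg$variant == "toeplitz")
    sprintf("%s_D%d", rcnCfg$variant, rcnCfg$D) else rcnCfg$variant
  saveCheckpoint(fit$model, file.path(outputDir, sprintf("rcn_%s.rds", tag)))
  utils::write.csv(fit$history,
                   file.path(outputDir, sprintf("rcn_%s_history.csv", tag)),
                   row.names = FALSE)
  message("rcn (", tag, "): best validation accuracy ",
          sprintf("%.3f", max(fit$history$val_accuracy)))
  invisible(fit$history)
}

#' Predict a dataset split and write the prediction table
#'
#' @param dataDir dataset directory.
#' @param modelDir directory holding `encoder.rds` and the rcn checkpoint.
#' @param outPath output CSV path.
#' @param split which manifest split to predict (default `"test"`).
#' @param rcnCheckpoint checkpoint file name; defaults to the single
#'   `rcn_*.rds` present.
#' @return The prediction table, invisibly.
#' @export
cmdPredict <- function(dataDir, modelDir, outPath, split = "test",
                       rcnCheckpoint = NULL) {
  encPath <- file.path(modelDir, "encoder.rds")
  if (!file.exists(encPath)) stop("missing checkpoint: ", encPath)
  if (is.null(rcnCheckpoint)) {
    cand <- list.files(modelDir, pattern = "^rcn_.*\\.rds$")
    if (length(cand) != 1L)
      stop("specify rcnCheckpoint: found ", length(cand), " rcn checkpoints")
    rcnCheckpoint <- cand
  }
  rcnPath <- file.path(modelDir, rcnCheckpoint)
  if (!file.exists(rcnPath)) stop("missing checkpoint: ", rcnPath)
  ds <- .load_dataset_dir(dataDir)
  ids <- ds$manifest$stack_id[ds$manifest$split == split]
  tab <- predictStacks(loadCheckpoint(encPath), loadCheckpoint(rcnPath),
                       ds$stacks[ids])
  writePredictions(tab, outPath)
  invisible(tab)
}

#' Evaluate a prediction table against dataset ground truth
#'
#' Writes the composite JSON report and a per-stack signed boundary error
#' CSV next to it.
#'
#' @param predictionsPath prediction CSV from [cmdPredict()].
#' @param dataDir dataset directory (for truth labels and manifest).
#' @param outPath output JSON report path.
#' @return The report list, invisibly.
#' @export
cmdEvaluate <- function(predictionsPath, dataDir, outPath) {
  if (!file.exists(predictionsPath))
    stop("predictions file not found: ", predictionsPath)
  preds <- readPredictions(predictionsPath)
  manifest <- utils::read.csv(file.path(dataDir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  ids <- unique(preds$stack_id)
  # evaluation is scoped to the stacks the prediction run covered
  manifest <- manifest[manifest$stack_id %in% ids, , drop = FALSE]
  labels <- list()
  for (id in ids) {
    lp <- file.path(dataDir, "labels", paste0(id, ".csv"))
    if (!file.exists(lp)) stop("truth labels not found: ", lp)
    labels[[id]] <- readLabels(lp, stackId = id)
  }
  report <- evaluateRun(preds, labels, manifest, path = outPath)
  utils::write.csv(report$boundaries$errors,
                   sub("\\.json$", "_boundary_errors.csv", outPath),
                   row.names = FALSE)
  invisible(report)
}

#' Run the full simulate-train-predict-evaluate loop in memory
#'
#' Convenience wrapper used by the examples and the acceptance analysis: a
#' single seed fans out to the simulator, encoder and sequence-model stages
#' by fixed offsets. Returns the evaluation report together with the
#' single-image (encoder-only) baseline accuracy on the same test slices, so
#' the sequence model can be compared against it.
#'
#' @param datasetCfg a [syntheticDatasetConfig()].
#' @param encoderCfg an [encoderConfig()].
#' @param rcnCfg an [rcnConfig()].
#' @param seed global seed; when not NULL it overrides the three configs'
#'   seeds with `seed`, `seed + 1000`, `seed + 2000`.
#' @param verbose print stage progress.
#' @return A list with `report` (see [evaluateRun()]), `encoder_accuracy`
#'   (single-slice baseline on test slices), `rcn_accuracy`,
#'   `encoder_history`, `rcn_history`, `predictions`, and the dataset
#'   `manifest`.
#' @export
runPipeline <- function(datasetCfg = syntheticDatasetConfig(),
                        encoderCfg = encoderConfig(),
                        rcnCfg = rcnConfig(epochs = 60L),
                        seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) {
    datasetCfg$seed <- as.integer(seed)
    encoderCfg$seed <- as.integer(seed + 1000L)
    rcnCfg$seed <- as.integer(seed + 2000L)
  }
  ds <- generateDataset(datasetCfg, render = TRUE)
  man <- ds$manifest
  stacks <- lapply(ds$stacks, `[[`, "stack")
  labels <- lapply(ds$stacks, `[[`, "labels")
  names(stacks) <- names(labels) <- man$stack_id
  pick <- function(split) man$stack_id[man$split == split]
  slices_of <- function(ids) list(
    images = do.call(c, lapply(stacks[ids], function(s) s@slices)),
    labels = unlist(lapply(labels[ids], function(l) l@labels)))
  tr <- slices_of(pick("train")); va <- slices_of(pick("val"))
  if (verbose) message("training slice encoder on ", length(tr$images),
                       " slices")
  efit <- trainEncoder(buildEncoder(encoderCfg), tr$images, tr$labels,
                       va$images, va$labels)
  encoder <- efit$encoder
  feats <- lapply(stacks, function(st) extractFeatures(encoder, st))
  if (verbose) message("training ", rcnCfg$variant, " sequence model on ",
                       length(pick("train")), " stacks")
  rfit <- trainRCN(buildRCN(rcnCfg), feats[pick("train")],
                   labels[pick("train")], feats[pick("val")],
                   labels[pick("val")])
  test_ids <- pick("test")
  tab <- predictStacks(encoder, rfit$model, stacks[test_ids])
  report <- evaluateRun(tab, labels[test_ids],
                        man[man$split == "test", , drop = FALSE])
  te <- slices_of(test_ids)
  enc_probs <- classifySlices(encoder, te$images)
  enc_acc <- mean(max.col(enc_probs, ties.method = "first") - 1L == te$labels)
  list(report = report, encoder_accuracy = enc_acc,
       rcn_accuracy = report$classification$accuracy,
       encoder_history = efit$history, rcn_history = rfit$history,
       predictions = tab, manifest = man)
}
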