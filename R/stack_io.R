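#' Natural (numeric-aware) sort of file names
#'
#' Orders strings so that embedded integers compare numerically: `s2` sorts
#' before `s10`. Clinical stack exports number their slices, and plain
#' lexicographic order would misplace `s10` before `s2`.
#'
#' @param x character vector.
#' @return `x` reordered; the ordering is total and deterministic (ties on
#'   the numeric key fall back to plain string order).
#' @export
#' @examples
#' naturalSort(c("s10.png", "s2.png", "s1.png"))
naturalSort <- function(x) {
  pad <- function(s) {
    m <- gregexpr("\\d+", s)
    parts <- regmatches(s, m)[[1]]
    if (length(parts))
      regmatches(s, m) <- list(sprintf("%020d", as.numeric(parts)))
    s
  }
  key <- vapply(x, pad, character(1), USE.NAMES = FALSE)
  x[order(key, x, method = "radix")]
}

.read_slice_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
    png = png::readPNG(f),
    tif = ,
    tiff = tiff::readTIFF(f),
    stop("unsupported slice file type: ", f))
  .to_gray(img)
}

# multi-channel -> channel mean; readPNG/readTIFF already scale to [0, 1]
.to_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  storage.mode(img) <- "double"
  img
}

#' Read an RCM stack from a multi-page TIFF or a directory of slice images
#'
#' Slices are ordered by page index (multi-page TIFF) or by natural sort of
#' file names (directory of PNG/TIFF files). Multi-channel images are reduced
#' to a single channel by the channel mean; pixel values are mapped to
#' \[0, 1\] by dividing by the maximum of the stored integer type.
#'
#' @param path a multi-page TIFF file, or a directory containing one image
#'   file per slice.
#' @param axialStep positive depth step between consecutive slices (um). The
#'   axial step is never inferred from the file: acquisition steps vary
#'   between 1.5 and 5 um and the files do not record them reliably.
#' @param depthOrigin depth of the first (shallowest) slice (um).
#' @param stackId,subjectId identifiers; default `stackId` is the file or
#'   directory base name.
#' @return An [RCMStack].
#' @export
readStack <- function(path, axialStep, depthOrigin = 0,
                      stackId = NULL, subjectId = "subject") {
  stopifnot(is.numeric(axialStep), length(axialStep) == 1L, axialStep > 0)
  if (is.null(stackId))
    stackId <- tools::file_path_sans_ext(basename(path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = FALSE)
    if (length(files) == 0L) stop("no slices found in ", path)
    files <- naturalSort(files)
    slices <- lapply(file.path(path, files), .read_slice_file)
  } else {
    if (!file.exists(path)) stop("no slices found: ", path, " does not exist")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L) stop("no slices found in ", path)
    slices <- lapply(pages, .to_gray)
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop("ragged stack: slices in ", path, " have differing dimensions")
  RCMStack(slices, axialStep = axialStep, depthOrigin = depthOrigin,
           stackId = stackId, subjectId = subjectId)
}

#' Write an RCM stack as a multi-page TIFF
#'
#' Pixel values are quantized to the requested bit depth. Stacks produced by
#' [generateStack()] are already on the 16-bit grid, so a write/read
#' round-trip of synthetic data is lossless.
#'
#' @param stack an [RCMStack].
#' @param path output file path.
#' @param bitsPerSample 8 or 16.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, bitsPerSample = 16L) {
  stopifnot(is(stack, "RCMStack"), bitsPerSample %in% c(8L, 16L))
  slices <- lapply(stack@slices, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(slices, path, bits.per.sample = as.integer(bitsPerSample))
  invisible(path)
}

.STRATUM_CODES <- c(stratum_corneum = 0L, epidermis = 0L, dej = 1L, dermis = 2L)

#' Read a per-slice strata label file
#'
#' Accepts CSV or TSV (auto-detected) with columns `(slice_index, label)`, an
#' optional header, and label strings from
#' `{stratum_corneum, epidermis, DEJ, dermis}` (case-insensitive; spaces or
#' hyphens in "stratum corneum" are tolerated). Rows are sorted by
#' `slice_index` (0-based).
#'
#' @param path label file.
#' @param mergeSC merge stratum corneum into the epidermis class (default
#'   TRUE, matching the 3-way classification task); with `mergeSC = FALSE` a
#'   stratum-corneum row is an error since the ordinal code space only covers
#'   the three modeled strata.
#' @param stackId identifier for the returned sequence; default the file base
#'   name.
#' @return A [StrataLabelSequence].
#' @export
readLabels <- function(path, mergeSC = TRUE, stackId = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  if (is.null(stackId)) stackId <- tools::file_path_sans_ext(basename(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  hdr <- grepl("[A-Za-z]", strsplit(first, sep, fixed = TRUE)[[1]][1])
  df <- utils::read.table(path, sep = sep, header = hdr,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) < 2L) stop("label file must have columns (slice_index, label)")
  idx <- as.integer(df[[1]])
  if (anyNA(idx)) stop("non-integer slice_index in ", path)
  if (anyDuplicated(idx)) stop("duplicate slice_index in ", path)
  raw <- tolower(gsub("[ -]", "_", trimws(as.character(df[[2]]))))
  unknown <- setdiff(unique(raw), names(.STRATUM_CODES))
  if (length(unknown))
    stop("unknown stratum label: ", paste(unknown, collapse = ", "))
  if (!mergeSC && any(raw == "stratum_corneum"))
    stop("stratum_corneum labels present but mergeSC = FALSE")
  ord <- order(idx)
  StrataLabelSequence(.STRATUM_CODES[raw][ord], stackId = stackId)
}

#' Pad and mask a batch of feature sequences
#'
#' Sequences longer than `maxLen` are clipped to their first `maxLen`
#' (shallowest) slices; shorter sequences are zero-padded at the tail. The
#' mask marks real slices `TRUE`. The default `maxLen` of 71 matches the
#' longest supported acquisition (a 101-slice stack is clipped to 71).
#'
#' @param featureSequences non-empty list of [FeatureSequence] objects with a
#'   common embedding dimension.
#' @param maxLen positive integer maximum sequence length.
#' @return A list with `batch` (array, stacks x maxLen x dim), `mask` (logical
#'   matrix, stacks x maxLen), `lengths` (clipped true lengths) and
#'   `stackIds`.
#' @export
padAndMask <- function(featureSequences, maxLen = 71L) {
  if (length(featureSequences) == 0L)
    stop("empty input: need at least one feature sequence")
  stopifnot(maxLen >= 1L)
  d <- unique(vapply(featureSequences, function(f) ncol(f@features), integer(1)))
  if (length(d) != 1L) stop("feature sequences have differing dimensions")
  B <- length(featureSequences)
  batch <- array(0, dim = c(B, maxLen, d))
  mask <- matrix(FALSE, B, maxLen)
  lens <- integer(B)
  for (b in seq_len(B)) {
    f <- featureSequences[[b]]@features
    n <- min(nrow(f), maxLen)
    batch[b, seq_len(n), ] <- f[seq_len(n), , drop = FALSE]
    mask[b, seq_len(n)] <- TRUE
    lens[b] <- n
  }
  list(batch = batch, mask = mask, lengths = lens,
       stackIds = vapply(featureSequences, stackId, character(1)))
}

.PRED_COLS <- c("stack_id", "slice_index", "depth_um", "p_epidermis",
                "p_DEJ", "p_dermis", "argmax_label", "postprocessed_label")

#' Validate a per-slice prediction table
#'
#' Checks the exact column schema, that each probability row sums to 1 within
#' 1e-6, and that `slice_index` is strictly increasing within each stack.
#'
#' @param table data.frame of per-slice predictions.
#' @return The table, invisibly; errors on violation.
#' @export
validatePredictionTable <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("prediction table must be a non-empty data.frame")
  if (!identical(names(table), .PRED_COLS))
    stop("prediction table columns must be exactly: ",
         paste(.PRED_COLS, collapse = ", "))
  p <- as.matrix(table[, c("p_epidermis", "p_DEJ", "p_dermis")])
  if (any(p < 0)) stop("negative class probability in prediction table")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("class probabilities must sum to 1 within 1e-6")
  for (sid in unique(table$stack_id)) {
    si <- table$slice_index[table$stack_id == sid]
    if (any(diff(si) <= 0))
      stop("slice_index must be strictly increasing within stack ", sid)
  }
  invisible(table)
}

#' Write (or read) a prediction table as CSV
#'
#' Probabilities are written at full double precision so that a write/read
#' round-trip agrees within 1e-9.
#'
#' @param table a valid prediction table (see [validatePredictionTable()]).
#' @param path output CSV path.
#' @return `path` invisibly (`writePredictions`); the table
#'   (`readPredictions`).
#' @export
writePredictions <- function(table, path) {
  validatePredictionTable(table)
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = "stack_id", integer = c("slice_index", "argmax_label",
                                        "postprocessed_label"))))
  validatePredictionTable(df)
}
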