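# Band-pass filtering, segmentation, normalization and train/test splitting.

#' Band-pass filter a recording
#'
#' Removes sub-10 Hz energy (hand-movement contamination) and energy above
#' 800 Hz (irrelevant for texture perception, potentially sensor noise)
#' with a 4th-order Butterworth band-pass applied forward-backward
#' (zero phase shift). Output length equals input length.
#'
#' @param recording a [VibrationRecording-class].
#' @param lowHz lower edge of the pass band (default 10 Hz).
#' @param highHz upper edge of the pass band (default 800 Hz).
#' @return The filtered [VibrationRecording-class].
#' @examples
#' lib <- makeMaterialLibrary(seed = 1)
#' pp <- makeParticipants(seed = 1)
#' rec <- synthRecording(lib, "m001", pp[1, ], durationS = 1, seed = 3)
#' filt <- bandpassFilter(rec)
#' @export
bandpassFilter <- function(recording, lowHz = 10, highHz = 800) {
  ny <- recording@rateHz / 2
  if (!(lowHz > 0 && lowHz < highHz && highHz < ny))
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g)",
                 lowHz, highHz, ny))
  bf <- signal::butter(4, c(lowHz, highHz) / ny, type = "pass")
  y <- signal::filtfilt(bf, recording@samples)
  initialize(recording, samples = as.numeric(y))
}

#' Segment a recording into fixed-length windows
#'
#' Tiles the trace into contiguous, non-overlapping windows of `windowMs`
#' milliseconds (80 ms at 3200 Hz gives the canonical 256-sample windows,
#' 125 of them for a 10 s trace). The window length must divide the
#' recording length exactly.
#'
#' @param recording a [VibrationRecording-class].
#' @param windowMs window length in milliseconds (default 80).
#' @return A [SegmentSet-class] with the recording's provenance carried into
#'   each segment's metadata.
#' @export
segmentRecording <- function(recording, windowMs = 80) {
  L <- round(windowMs * recording@rateHz / 1000)
  n <- length(recording@samples)
  if (L < 1L) stop("window shorter than one sample")
  if (n %% L != 0L)
    stop(sprintf(
      "window of %d samples does not tile the %d-sample recording; truncate %d samples first",
      L, n, n %% L))
  nSeg <- n %/% L
  mat <- matrix(recording@samples, nrow = L, ncol = nSeg)
  meta <- data.frame(
    participant_id = recording@participantId,
    material_id = recording@materialId,
    category_id = recording@categoryId,
    segment_index = seq_len(nSeg))
  SegmentSet(mat, meta, rateHz = recording@rateHz)
}

#' Combine several SegmentSets into one
#'
#' @param sets list of [SegmentSet-class] objects with equal window length
#'   and sampling rate.
#' @return One combined [SegmentSet-class].
#' @export
combineSegmentSets <- function(sets) {
  if (!length(sets)) stop("empty set list")
  L <- nrow(sets[[1]])
  rate <- segmentRate(sets[[1]])
  if (any(vapply(sets, nrow, 0L) != L))
    stop("window lengths differ between sets")
  data <- do.call(cbind, lapply(sets, segmentData))
  meta <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(SummarizedExperiment::colData(s))))
  SegmentSet(data, meta, rateHz = rate)
}

#' Normalize segments to \[0, 1\]
#'
#' Applies one global affine map based on the training set's minimum and
#' maximum (the sigmoid output layer of the autoencoder requires targets in
#' \[0, 1\]). When `constants` is supplied (e.g. the training constants applied
#' to test data), values are mapped with those constants and clipped to
#' \[0, 1\]; otherwise constants are computed from `x` and stored in its
#' metadata for later inversion.
#'
#' @param x a [SegmentSet-class].
#' @param constants optional `list(min =, max =)` from a previously
#'   normalized training set (see [normalizationConstants()]).
#' @return The normalized [SegmentSet-class] with constants in metadata.
#' @export
normalizeSegments <- function(x, constants = NULL) {
  d <- segmentData(x)
  if (is.null(constants)) {
    lo <- min(d); hi <- max(d)
    if (lo >= hi) stop("constant segment set cannot be normalized")
    y <- (d - lo) / (hi - lo)
  } else {
    lo <- constants$min; hi <- constants$max
    if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
      stop("invalid normalization constants")
    y <- pmin(pmax((d - lo) / (hi - lo), 0), 1)
  }
  SegmentSet(y, as.data.frame(SummarizedExperiment::colData(x)),
             rateHz = segmentRate(x),
             normalization = list(min = lo, max = hi))
}

#' Invert a normalization
#'
#' @param x a normalized [SegmentSet-class] carrying constants.
#' @return The [SegmentSet-class] on the original scale.
#' @export
denormalizeSegments <- function(x) {
  k <- normalizationConstants(x)
  if (is.null(k)) stop("no normalization constants stored")
  d <- segmentData(x) * (k$max - k$min) + k$min
  SegmentSet(d, as.data.frame(SummarizedExperiment::colData(x)),
             rateHz = segmentRate(x))
}

#' Random train/test split at the segment level
#'
#' Splits segments into disjoint, exhaustive train and test sets. The train
#' set holds `floor(trainFraction * N)` segments drawn uniformly at random;
#' the split is deterministic given `seed`. Segments of one material may
#' fall in both sets (segment-level, not grouped, splitting).
#'
#' @param x a [SegmentSet-class].
#' @param trainFraction fraction of segments for training (default 0.95).
#' @param seed integer seed.
#' @return `list(train =, test =)` of [SegmentSet-class] objects.
#' @export
splitSegments <- function(x, trainFraction = 0.95, seed = 1L) {
  if (!(trainFraction > 0 && trainFraction < 1))
    stop("'trainFraction' must lie strictly between 0 and 1")
  n <- nSegments(x)
  nTrain <- floor(trainFraction * n)
  idx <- withSeed(seed, sample.int(n, nTrain))
  list(train = x[, sort(idx)], test = x[, sort(setdiff(seq_len(n), idx))])
}
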