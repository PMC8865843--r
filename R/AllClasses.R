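#' @import methods
NULL

#' Canonical material category labels
#'
#' The seven everyday material categories used throughout the package, in
#' fixed order; category ids are 0-based indices into this vector.
#' @export
MATERIAL_CATEGORIES <- c("paper", "fabric", "animal", "stone", "plastic",
                         "wood", "metal")

#' Haptic descriptor labels
#'
#' The seven antagonist adjective-pair descriptors collected in the rating
#' experiment.
#' @export
HAPTIC_DESCRIPTORS <- c("roughness", "orderliness", "hardness", "temperature",
                        "elasticity", "friction", "texture")

#' MaterialLibrary: synthetic material specifications
#'
#' Holds, for every simulated material sample, its category membership, a
#' non-negative spectral envelope (gain per frequency bin over 0--1600 Hz)
#' obtained by jittering the category base envelope, and a 7-dimensional
#' latent attribute vector derived from the envelope that drives the rating
#' simulator. Category base envelopes are mixtures of Gaussian bumps inside
#' the 20--700 Hz analysis band and are pairwise distinct by construction.
#'
#' @slot materials data.frame with columns `material_id`, `category_id`.
#' @slot freq numeric vector of envelope frequency bins (Hz).
#' @slot envelopes matrix (materials x bins) of per-material envelope gains.
#' @slot categoryEnvelopes matrix (categories x bins) of base envelopes.
#' @slot attributes matrix (materials x 7) of latent haptic attributes.
#' @slot seed integer seed the library was generated from.
#' @exportClass MaterialLibrary
setClass("MaterialLibrary",
  representation(materials = "data.frame", freq = "numeric",
                 envelopes = "matrix", categoryEnvelopes = "matrix",
                 attributes = "matrix", seed = "integer"))

setValidity("MaterialLibrary", function(object) {
  msg <- character()
  if (any(object@envelopes < 0)) msg <- c(msg, "envelope gains must be >= 0")
  if (nrow(object@envelopes) != nrow(object@materials))
    msg <- c(msg, "one envelope row per material required")
  if (ncol(object@envelopes) != length(object@freq))
    msg <- c(msg, "envelope columns must match frequency bins")
  if (anyDuplicated(object@materials$material_id))
    msg <- c(msg, "material ids must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MaterialLibrary", function(object) {
  cat("MaterialLibrary:", nrow(object@materials), "materials in",
      length(unique(object@materials$category_id)), "categories\n")
  print(table(category = object@materials$category_id))
})

#' VibrationRecording: one acceleration trace
#'
#' A single (participant, material) acceleration recording with its sampling
#' rate and provenance labels. The canonical study recording is 10 s at
#' 3200 Hz, i.e. 32,000 samples.
#'
#' @slot samples numeric vector of acceleration amplitudes (arbitrary units).
#' @slot rateHz sampling rate in Hz.
#' @slot participantId integer participant identifier.
#' @slot materialId character material identifier.
#' @slot categoryId integer ground-truth category id (0-based).
#' @exportClass VibrationRecording
setClass("VibrationRecording",
  representation(samples = "numeric", rateHz = "numeric",
                 participantId = "integer", materialId = "character",
                 categoryId = "integer"))

setValidity("VibrationRecording", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (!length(object@samples)) msg <- c(msg, "empty trace")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VibrationRecording", function(object) {
  cat(sprintf(
    "VibrationRecording: material %s (category %d), participant %d\n",
    object@materialId, object@categoryId, object@participantId))
  cat(sprintf("  %d samples at %g Hz (%.3f s)\n", length(object@samples),
              object@rateHz, length(object@samples) / object@rateHz))
})

#' SegmentSet: fixed-length signal windows
#'
#' A [SummarizedExperiment::SummarizedExperiment] specialisation whose single
#' assay holds one fixed-length signal window per column (rows are time
#' samples). `colData` carries per-segment provenance (`participant_id`,
#' `material_id`, `category_id`, `segment_index`); `metadata()` carries the
#' sampling rate and, once [normalizeSegments()] has run, the global
#' normalization constants.
#'
#' @exportClass SegmentSet
#' @import SummarizedExperiment
setClass("SegmentSet", contains = "SummarizedExperiment")

setValidity("SegmentSet", function(object) {
  msg <- character()
  need <- c("participant_id", "material_id", "category_id", "segment_index")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentSet
#'
#' @param data matrix, one segment per column (rows are time samples).
#' @param meta data.frame/DataFrame with one row per segment holding
#'   `participant_id`, `material_id`, `category_id`, `segment_index`.
#' @param rateHz sampling rate of the segments in Hz.
#' @param normalization optional list with elements `min` and `max`.
#' @return A [SegmentSet-class] object.
#' @export
SegmentSet <- function(data, meta, rateHz,
                       normalization = NULL) {
  data <- as.matrix(data)
  if (nrow(as.data.frame(meta)) != ncol(data))
    stop("metadata row count must equal segment count")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = data),
    colData = S4Vectors::DataFrame(meta))
  md <- list(rateHz = rateHz)
  if (!is.null(normalization)) md$normalization <- normalization
  S4Vectors::metadata(se) <- md
  new("SegmentSet", se)
}

#' @describeIn SegmentSet number of segments.
#' @param x a `SegmentSet`.
#' @export
nSegments <- function(x) ncol(x)

#' @describeIn SegmentSet segment matrix (time samples x segments).
#' @export
segmentData <- function(x) SummarizedExperiment::assay(x, "signal")

#' @describeIn SegmentSet stored normalization constants (or NULL).
#' @export
normalizationConstants <- function(x) S4Vectors::metadata(x)$normalization

#' @describeIn SegmentSet sampling rate in Hz.
#' @export
segmentRate <- function(x) S4Vectors::metadata(x)$rateHz

#' AutoencoderSpec: architecture description
#'
#' Describes the 1-D convolutional autoencoder: four encoder convolutions
#' (kernel 5, same padding) each followed by a factor-4 max pool, driving the
#' time axis through 256 -> 64 -> 16 -> 4 -> 1, a `latentDim`-feature code at
#' the bottleneck, and a mirrored decoder using step-repetition upsampling
#' with a final sigmoid convolution back to 256 samples. Feature counts are
#' clamped to be at least `latentDim` so no intermediate layer is narrower
#' than the bottleneck.
#'
#' @slot inputLength integer, window length in samples (256).
#' @slot latentDim integer bottleneck dimensionality.
#' @slot encoderFeatures integer vector of 4 encoder feature counts.
#' @slot decoderFeatures integer vector of 5 decoder feature counts (last 1).
#' @slot kernelSize integer convolution kernel size (5).
#' @slot poolSize integer max-pool / upsample factor (4).
#' @exportClass AutoencoderSpec
setClass("AutoencoderSpec",
  representation(inputLength = "integer", latentDim = "integer",
                 encoderFeatures = "integer", decoderFeatures = "integer",
                 kernelSize = "integer", poolSize = "integer"))

setValidity("AutoencoderSpec", function(object) {
  msg <- character()
  d <- object@latentDim
  if (d < 1L || d > object@inputLength)
    msg <- c(msg, "latentDim must lie in 1..inputLength")
  if (length(object@encoderFeatures) != 4L)
    msg <- c(msg, "four encoder layers required")
  if (length(object@decoderFeatures) != 5L ||
      object@decoderFeatures[5L] != 1L)
    msg <- c(msg, "five decoder layers ending in 1 feature required")
  if (any(object@encoderFeatures < d) ||
      any(object@decoderFeatures[-5L] < d))
    msg <- c(msg, "layer feature counts must be >= latentDim")
  if (object@encoderFeatures[4L] != d)
    msg <- c(msg, "final encoder layer must output latentDim features")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AutoencoderSpec", function(object) {
  cat(sprintf("AutoencoderSpec: %d -> code(%d) -> %d, compression %.2f%%\n",
              object@inputLength, object@latentDim, object@inputLength,
              100 * object@latentDim / object@inputLength))
  cat("  encoder features:", paste(object@encoderFeatures, collapse = ", "),
      "| decoder features:",
      paste(object@decoderFeatures, collapse = ", "), "\n")
})

#' TrainedAutoencoder: fitted model
#'
#' A trained model: its [AutoencoderSpec-class], learned weights, and the
#' per-epoch mean-absolute-error training report.
#'
#' @slot spec the architecture specification.
#' @slot weights list of 9 layers, each `list(W, b)`.
#' @slot trainingReport data.frame with columns `epoch`, `trainMAE`,
#'   `valMAE` (NA when no validation set was supplied).
#' @slot seed integer training seed.
#' @exportClass TrainedAutoencoder
setClass("TrainedAutoencoder",
  representation(spec = "AutoencoderSpec", weights = "list",
                 trainingReport = "data.frame", seed = "integer"))

setMethod("show", "TrainedAutoencoder", function(object) {
  rep <- object@trainingReport
  cat(sprintf("TrainedAutoencoder (latentDim %d), %d epochs\n",
              object@spec@latentDim, nrow(rep)))
  if (nrow(rep))
    cat(sprintf("  final train MAE %.5f, validation MAE %s\n",
                rep$trainMAE[nrow(rep)],
                ifelse(is.na(rep$valMAE[nrow(rep)]), "NA",
                       sprintf("%.5f", rep$valMAE[nrow(rep)]))))
})

#' @describeIn TrainedAutoencoder per-epoch loss curves.
#' @param object a `TrainedAutoencoder`.
#' @export
trainingReport <- function(object) object@trainingReport

#' LatentPCSpace: principal components of the latent codes
#'
#' PCA basis over latent codes with explained-variance bookkeeping. `k` is
#' the smallest number of components whose cumulative explained variance
#' reaches the requested threshold; `projected` holds the centred codes
#' projected onto those `k` components.
#'
#' @slot rotation full loading matrix (d x d).
#' @slot center per-dimension means removed before projection.
#' @slot evr explained-variance ratios for all d components (sums to 1).
#' @slot k retained dimensionality.
#' @slot threshold the variance threshold used to pick `k`.
#' @slot projected matrix (segments x k) of projected codes.
#' @slot segmentInfo DataFrame of per-row provenance carried from the codes.
#' @exportClass LatentPCSpace
setClass("LatentPCSpace",
  representation(rotation = "matrix", center = "numeric", evr = "numeric",
                 k = "integer", threshold = "numeric", projected = "matrix",
                 segmentInfo = "DataFrame"))

setValidity("LatentPCSpace", function(object) {
  msg <- character()
  if (any(object@evr < -1e-12)) msg <- c(msg, "variance ratios must be >= 0")
  if (is.unsorted(rev(object@evr), strictly = FALSE) &&
      any(diff(object@evr) > 1e-8))
    msg <- c(msg, "variance ratios must be non-increasing")
  if (abs(sum(object@evr) - 1) > 1e-6)
    msg <- c(msg, "variance ratios must sum to 1")
  if (object@k < 1L || object@k > length(object@evr))
    msg <- c(msg, "k out of range")
  if (ncol(object@projected) != object@k)
    msg <- c(msg, "projected must have k columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LatentPCSpace", function(object) {
  cat(sprintf(
    "LatentPCSpace: %d of %d components retain %.1f%% of variance (threshold %g)\n",
    object@k, length(object@evr),
    100 * sum(object@evr[seq_len(object@k)]), object@threshold))
})

#' @describeIn LatentPCSpace explained-variance ratios.
#' @param object a `LatentPCSpace`.
#' @export
explainedVariance <- function(object) object@evr

#' @describeIn LatentPCSpace retained dimensionality.
#' @export
retainedDim <- function(object) object@k

#' @describeIn LatentPCSpace projected codes (segments x k).
#' @export
projectedCodes <- function(object) object@projected

#' DistanceMatrix: category-by-category dissimilarities
#'
#' A symmetric category-level dissimilarity matrix. The `latent` flavour
#' holds Euclidean distances between category centroids (zero diagonal); the
#' `perceptual` flavour holds rating-correlation distances
#' `delta = 2 * (1 - rho)` (diagonal reflects within-category dissimilarity
#' across distinct materials and need not be zero).
#'
#' @slot values symmetric numeric matrix with category dimnames.
#' @slot flavor `"latent"` or `"perceptual"`.
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(values = "matrix", flavor = "character"))

setValidity("DistanceMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
  if (is.null(rownames(v))) msg <- c(msg, "category labels required")
  if (!object@flavor %in% c("latent", "perceptual"))
    msg <- c(msg, "flavor must be 'latent' or 'perceptual'")
  if (object@flavor == "latent" && any(abs(diag(v)) > 1e-8))
    msg <- c(msg, "latent flavour requires a zero diagonal")
  if (object@flavor == "latent" && any(v < -1e-12))
    msg <- c(msg, "latent distances must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s flavour), %d categories\n",
              object@flavor, nrow(object@values)))
  print(round(object@values, 3))
})

#' @describeIn DistanceMatrix the raw matrix.
#' @param object a `DistanceMatrix`.
#' @export
distanceValues <- function(object) object@values

#' RatingTable: descriptor and category-similarity ratings
#'
#' Long-format rating data: per (participant, material) seven descriptor
#' ratings and seven category-similarity ratings, plus the ground-truth
#' material-category map used for bookkeeping.
#'
#' @slot descriptors data.frame (`participant_id`, `material_id`,
#'   `descriptor`, `value`).
#' @slot categories data.frame (`participant_id`, `material_id`, `category`,
#'   `similarity`).
#' @slot materials data.frame (`material_id`, `category_id`) ground truth.
#' @slot zTransformed logical; TRUE after [zTransform()].
#' @exportClass RatingTable
setClass("RatingTable",
  representation(descriptors = "data.frame", categories = "data.frame",
                 materials = "data.frame", zTransformed = "logical"))

setValidity("RatingTable", function(object) {
  msg <- character()
  if (!all(c("participant_id", "material_id", "descriptor", "value") %in%
           names(object@descriptors)))
    msg <- c(msg, "descriptor table misses required columns")
  if (!all(c("participant_id", "material_id", "category", "similarity") %in%
           names(object@categories)))
    msg <- c(msg, "category table misses required columns")
  if (length(unique(object@descriptors$descriptor)) != 7L)
    msg <- c(msg, "seven descriptors required")
  if (length(unique(object@categories$category)) != 7L)
    msg <- c(msg, "seven categories required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RatingTable", function(object) {
  cat(sprintf(
    "RatingTable: %d participants x %d materials (%sz-transformed)\n",
    length(unique(object@descriptors$participant_id)),
    length(unique(object@descriptors$material_id)),
    if (object@zTransformed) "" else "not "))
})

#' ClassificationResult: LOO classification plus bootstrap null
#'
#' @slot accuracy percent correct over all leave-one-material-per-category
#'   folds.
#' @slot predictions data.frame (`fold`, `material_id`, `true`, `predicted`).
#' @slot labelSource `"ground_truth"`, `"perceptual"`, or `"custom"`.
#' @slot nullMean mean accuracy (percent) under label shuffling (NA before
#'   [bootstrapNull()]).
#' @slot nullCI length-2 numeric, 2.5th/97.5th percentile of the null.
#' @slot nShuffles integer number of shuffles behind the null.
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  representation(accuracy = "numeric", predictions = "data.frame",
                 labelSource = "character", nullMean = "numeric",
                 nullCI = "numeric", nShuffles = "integer"))

setValidity("ClassificationResult", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 100)
    msg <- c(msg, "accuracy must lie in [0, 100]")
  if (!is.na(object@nullMean) &&
      (object@nullMean < object@nullCI[1] - 1e-9 ||
       object@nullMean > object@nullCI[2] + 1e-9))
    msg <- c(msg, "null mean must lie inside the null CI")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult (%s labels): accuracy %.1f%%\n",
              object@labelSource, object@accuracy))
  if (!is.na(object@nullMean))
    cat(sprintf("  bootstrap null: mean %.1f%%, 95%% CI [%.1f, %.1f] (%d shuffles)\n",
                object@nullMean, object@nullCI[1], object@nullCI[2],
                object@nShuffles))
})

#' @describeIn ClassificationResult accuracy in percent.
#' @param object a `ClassificationResult`.
#' @export
accuracy <- function(object) object@accuracy

#' TuningCurveSet: frequency tuning of latent dimensions
#'
#' Sensitivity of each latent-PC dimension to sinusoidal probes as a
#' function of temporal frequency, each dimension min-max normalized to
#' \[0, 1\]; with the weighted-mean-frequency summary and the low/high
#' k-means cluster assignment once computed.
#'
#' @slot frequencies Hz grid of the probe bank.
#' @slot sensitivity matrix (dimensions x frequencies) in \[0, 1\].
#' @slot summaryHz sensitivity-weighted mean frequency per dimension.
#' @slot cluster factor (`low`/`high`) per dimension (may be empty).
#' @slot excluded integer indices of degenerate (flat) dimensions.
#' @exportClass TuningCurveSet
setClass("TuningCurveSet",
  representation(frequencies = "numeric", sensitivity = "matrix",
                 summaryHz = "numeric", cluster = "factor",
                 excluded = "integer"))

setValidity("TuningCurveSet", function(object) {
  msg <- character()
  s <- object@sensitivity
  if (ncol(s) != length(object@frequencies))
    msg <- c(msg, "sensitivity columns must match frequency grid")
  keep <- setdiff(seq_len(nrow(s)), object@excluded)
  if (length(keep)) {
    rng <- t(apply(s[keep, , drop = FALSE], 1, range))
    if (any(abs(rng[, 1]) > 1e-8) || any(abs(rng[, 2] - 1) > 1e-8))
      msg <- c(msg, "each non-degenerate dimension must span [0, 1]")
  }
  ok <- !is.na(object@summaryHz)
  if (any(object@summaryHz[ok] < min(object@frequencies) - 1e-9) ||
      any(object@summaryHz[ok] > max(object@frequencies) + 1e-9))
    msg <- c(msg, "tuning summaries must lie within the frequency grid")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TuningCurveSet", function(object) {
  cat(sprintf("TuningCurveSet: %d dimensions x %d frequencies (%g-%g Hz)\n",
              nrow(object@sensitivity), length(object@frequencies),
              min(object@frequencies), max(object@frequencies)))
  if (length(object@cluster))
    print(table(cluster = object@cluster))
})

#' @describeIn TuningCurveSet per-dimension weighted-mean frequencies.
#' @param object a `TuningCurveSet`.
#' @export
tuningSummaries <- function(object) object@summaryHz
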