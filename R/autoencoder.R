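# R-level interface to the convolutional autoencoder.

#' Build an autoencoder architecture
#'
#' Four encoder convolutions (kernel 5, same padding, ReLU), each followed by
#' a factor-4 max pool, take a 256-sample window through the time schedule
#' 256 -> 64 -> 16 -> 4 -> 1, ending in a `latentDim`-feature code. The
#' decoder mirrors the encoder with step-repetition upsampling (each time
#' step repeated four times) and a final sigmoid convolution back to one
#' 256-sample channel. Default feature counts are 64, 32, 16, `latentDim`
#' for the encoder and 16, 16, 32, 64, 1 for the decoder; for wider
#' bottlenecks every intermediate feature count is clamped to at least
#' `latentDim`, so no layer is narrower than the code.
#'
#' @param latentDim bottleneck dimensionality, 1..256 (default 16, i.e. a
#'   6.25\% compression rate).
#' @return An [AutoencoderSpec-class].
#' @examples
#' buildAutoencoder(16)
#' @export
buildAutoencoder <- function(latentDim = 16L) {
  if (!is.numeric(latentDim) || length(latentDim) != 1L ||
      latentDim < 1 || latentDim > 256 || latentDim != round(latentDim))
    stop("'latentDim' must be an integer in 1..256")
  d <- as.integer(latentDim)
  new("AutoencoderSpec",
      inputLength = 256L, latentDim = d,
      encoderFeatures = as.integer(pmax(c(64L, 32L, 16L, d), d)),
      decoderFeatures = as.integer(c(pmax(c(16L, 16L, 32L, 64L), d), 1L)),
      kernelSize = 5L, poolSize = 4L)
}

#' Layer-by-layer shape schedule of an architecture
#'
#' Enumerates every convolution's input/output time length and feature
#' count, useful to audit that the realized parameter shapes follow the
#' intended schedule.
#'
#' @param spec an [AutoencoderSpec-class].
#' @return data.frame with columns `layer`, `stage`, `timeIn`, `featIn`,
#'   `timeOut`, `featOut`.
#' @export
autoencoderShapes <- function(spec) {
  encT <- c(256L, 64L, 16L, 4L)
  decT <- c(1L, 4L, 16L, 64L, 256L)
  encIn <- c(1L, spec@encoderFeatures[1:3])
  decIn <- c(spec@latentDim, spec@decoderFeatures[1:4])
  data.frame(
    layer = c(paste0("enc", 1:4), paste0("dec", 1:5)),
    stage = c(rep("encoder", 4), rep("decoder", 5)),
    timeIn = c(encT, decT),
    featIn = c(encIn, decIn),
    timeOut = c(encT, decT),
    featOut = c(spec@encoderFeatures, spec@decoderFeatures))
}

# Glorot-uniform initial weights for every conv layer
initWeights <- function(spec, seed) {
  sh <- autoencoderShapes(spec)
  k <- spec@kernelSize
  withSeed(seed, {
    lapply(seq_len(nrow(sh)), function(i) {
      fanIn <- sh$featIn[i] * k
      fanOut <- sh$featOut[i] * k
      lim <- sqrt(6 / (fanIn + fanOut))
      list(W = matrix(runif(sh$featOut[i] * fanIn, -lim, lim),
                      sh$featOut[i], fanIn),
           b = rep(0, sh$featOut[i]))
    })
  })
}

checkNormalized <- function(x, what) {
  d <- segmentData(x)
  if (min(d) < 0 || max(d) > 1)
    stop(sprintf(
      "%s segments must be normalized to [0, 1]; run normalizeSegments()",
      what))
  invisible(TRUE)
}

#' Train the autoencoder
#'
#' Minimizes the mean absolute error (MAE) between input and reconstruction
#' over `epochs` epochs (50 in the canonical setting) with the Adam
#' optimizer. Segments must be normalized to \[0, 1\] to match the sigmoid
#' output layer. Weight initialisation, batch shuffling and hence the whole
#' loss curve are deterministic given `seed`.
#'
#' @param spec an [AutoencoderSpec-class] from [buildAutoencoder()].
#' @param train normalized training [SegmentSet-class].
#' @param validation optional normalized validation [SegmentSet-class]; its
#'   per-epoch MAE is tracked in the training report.
#' @param epochs number of epochs (default 50).
#' @param batchSize minibatch size (default 128).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed.
#' @return A [TrainedAutoencoder-class].
#' @export
trainAutoencoder <- function(spec, train, validation = NULL, epochs = 50L,
                             batchSize = 128L, lr = 1e-3, seed = 1L) {
  checkNormalized(train, "training")
  if (!is.null(validation)) checkNormalized(validation, "validation")
  if (nrow(train) != spec@inputLength)
    stop(sprintf("segments must have %d samples", spec@inputLength))
  w0 <- initWeights(spec, seed)
  Xval <- if (is.null(validation))
    matrix(0, spec@inputLength, 0) else segmentData(validation)
  fit <- cpp_ae_train(w0, segmentData(train), Xval,
                      spec@latentDim, as.integer(epochs),
                      as.integer(batchSize), lr, as.integer(seed))
  report <- data.frame(epoch = seq_len(epochs),
                       trainMAE = fit$trainMAE, valMAE = fit$valMAE)
  new("TrainedAutoencoder", spec = spec, weights = fit$weights,
      trainingReport = report, seed = as.integer(seed))
}

#' Encode segments into latent codes
#'
#' Runs the encoder half of the network; each 256-sample window maps to a
#' single `latentDim`-feature point (the code at the bottleneck).
#'
#' @param model a [TrainedAutoencoder-class].
#' @param segments a normalized [SegmentSet-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] whose `code`
#'   assay is `latentDim x N`, with the segments' provenance as `colData`.
#' @export
encodeSegments <- function(model, segments) {
  if (nrow(segments) != model@spec@inputLength)
    stop(sprintf("segments must have %d samples", model@spec@inputLength))
  out <- cpp_ae_forward(model@weights, segmentData(segments),
                        model@spec@latentDim)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(code = out$code),
    colData = SummarizedExperiment::colData(segments))
  se
}

#' Reconstruct segments through the full autoencoder
#'
#' @inheritParams encodeSegments
#' @return A [SegmentSet-class] holding the reconstructions (values in
#'   (0, 1), the sigmoid range).
#' @export
reconstructSegments <- function(model, segments) {
  out <- cpp_ae_forward(model@weights, segmentData(segments),
                        model@spec@latentDim)
  SegmentSet(out$recon,
             as.data.frame(SummarizedExperiment::colData(segments)),
             rateHz = segmentRate(segments),
             normalization = normalizationConstants(segments))
}

# mean squared per-column correlation between two segment matrices;
# columns with zero input variance are excluded (warning), columns whose
# reconstruction is constant contribute 0
segmentR2 <- function(x, y) {
  sds <- apply(x, 2, sd)
  bad <- which(sds == 0)
  if (length(bad)) {
    warning(sprintf("%d constant segment(s) excluded from R2", length(bad)))
    x <- x[, -bad, drop = FALSE]
    y <- y[, -bad, drop = FALSE]
  }
  if (!ncol(x)) stop("no non-constant segments left")
  r <- vapply(seq_len(ncol(x)), function(i)
    suppressWarnings(cor(x[, i], y[, i])), 0)
  r[is.na(r)] <- 0
  mean(r^2)
}

#' Reconstruction performance as fraction of variance explained
#'
#' For every segment, the Pearson correlation between input and
#' reconstruction is squared; the mean over segments is returned.
#' Constant (zero-variance) segments cannot be correlated and are excluded
#' with a warning.
#'
#' @inheritParams encodeSegments
#' @return Mean per-segment squared correlation, in \[0, 1\].
#' @export
reconstructionR2 <- function(model, segments) {
  segmentR2(segmentData(segments),
            segmentData(reconstructSegments(model, segments)))
}

#' Compression rate of a bottleneck
#'
#' Ratio between latent and input dimensionality, in percent; 16/256 gives
#' 6.25\%, 256/256 gives 100\% (no compression).
#'
#' @param latentDim bottleneck dimensionality (> 0).
#' @param inputDim input dimensionality (default 256).
#' @return The compression rate in percent.
#' @export
compressionRate <- function(latentDim, inputDim = 256L) {
  stopifnotScalar(latentDim, "latentDim", positive = TRUE)
  stopifnotScalar(inputDim, "inputDim", positive = TRUE)
  100 * latentDim / inputDim
}
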