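# Temporal-frequency tuning of the latent dimensions, probed with a bank of
# sinusoids, summarized by a sensitivity-weighted mean frequency, clustered
# into low/high groups and compared to tactile-afferent tuning bands.

#' Build a sinusoid probe bank
#'
#' Generates `n` frequencies on a uniform grid from 0 to `fMax` (830 points
#' over 0--800 Hz in the canonical probe, grid step ~0.96 Hz; the 0 Hz
#' endpoint is replaced by the first positive grid frequency since a true
#' DC probe is the constant baseline signal itself). Each frequency appears
#' at `nPhases` phase offsets; signals are offset to mid-range 0.5 so they
#' live in the normalized \[0, 1\] input domain.
#'
#' @param n number of frequencies (default 830).
#' @param fMax top frequency in Hz (default 800).
#' @param length window length in samples (default 256).
#' @param rateHz sampling rate in Hz (default 3200).
#' @param amplitude peak amplitude around the 0.5 offset (default 0.25,
#'   i.e. peak-to-peak 0.5); `0.5 + amplitude` must not exceed 1.
#' @param nPhases phase offsets per frequency (default 8).
#' @return A [SegmentSet-class] whose `colData` carries `frequency` and
#'   `phase` per probe.
#' @export
makeSinusoidBank <- function(n = 830L, fMax = 800, length = 256L,
                             rateHz = 3200, amplitude = 0.25,
                             nPhases = 8L) {
  if (fMax > rateHz / 2) stop("fMax exceeds the Nyquist frequency")
  if (0.5 + abs(amplitude) > 1 + 1e-12)
    stop("amplitude overflows the [0, 1] signal range")
  freqs <- seq(0, fMax, length.out = n)
  if (freqs[1] == 0) freqs[1] <- freqs[2]
  phases <- 2 * pi * (seq_len(nPhases) - 1L) / nPhases
  tt <- (seq_len(length) - 1L) / rateHz
  grid <- expand.grid(phase = phases, frequency = freqs)
  data <- vapply(seq_len(nrow(grid)),
                 function(i) 0.5 + amplitude *
                   sin(2 * pi * grid$frequency[i] * tt + grid$phase[i]),
                 numeric(length))
  meta <- data.frame(participant_id = 0L, material_id = "probe",
                     category_id = -1L, segment_index = seq_len(nrow(grid)),
                     frequency = grid$frequency, phase = grid$phase)
  SegmentSet(data, meta, rateHz = rateHz)
}

# encode a segment matrix through either a trained model (optionally into a
# PC space) or a user-supplied linear/probe encoder function
encodeProbe <- function(model, pcspace, data) {
  if (is.function(model)) {
    codes <- model(data)
  } else {
    codes <- t(cpp_ae_forward(model@weights, data,
                              model@spec@latentDim)$code)
  }
  if (!is.null(pcspace)) codes <- projectCodes(pcspace, codes)
  codes
}

#' Probe the temporal tuning of the latent dimensions
#'
#' Feeds the sinusoid bank through the encoder (and, if given, into the
#' latent PCs space) and defines the response of a dimension at a frequency
#' as the mean over phases of the absolute deviation of its projection from
#' the baseline response to the constant mid-range (0.5) signal. Each
#' dimension's curve is then min-max normalized to \[0, 1\]. Dimensions with
#' zero response range are flagged as degenerate and excluded from
#' clustering.
#'
#' @param model a [TrainedAutoencoder-class], or a function mapping a
#'   segment matrix (samples x N) to codes (N x d) — useful to probe
#'   hand-built encoders.
#' @param pcspace optional [LatentPCSpace-class]; when supplied, tuning is
#'   measured along its retained components.
#' @param bank a [SegmentSet-class] from [makeSinusoidBank()].
#' @return A [TuningCurveSet-class].
#' @export
probeTuning <- function(model, pcspace = NULL, bank) {
  cd <- SummarizedExperiment::colData(bank)
  if (!all(c("frequency", "phase") %in% colnames(cd)))
    stop("bank must carry frequency and phase metadata")
  L <- nrow(bank)
  baselineSig <- matrix(0.5, L, 1)
  base <- encodeProbe(model, pcspace, baselineSig)
  codes <- encodeProbe(model, pcspace, segmentData(bank))
  dev <- abs(sweep(codes, 2, as.numeric(base)))
  freqs <- sort(unique(cd$frequency))
  sens <- matrix(vapply(freqs, function(f)
    colMeans(dev[cd$frequency == f, , drop = FALSE]),
    numeric(ncol(dev))), nrow = ncol(dev))  # dims x frequencies
  rng <- apply(sens, 1, function(v) diff(range(v)))
  excluded <- which(rng <= .Machine$double.eps * 10)
  if (length(excluded))
    warning(sprintf("%d degenerate (flat) dimension(s) flagged",
                    length(excluded)))
  for (i in setdiff(seq_len(nrow(sens)), excluded))
    sens[i, ] <- (sens[i, ] - min(sens[i, ])) / diff(range(sens[i, ]))
  summ <- rep(NA_real_, nrow(sens))
  keep <- setdiff(seq_len(nrow(sens)), excluded)
  summ[keep] <- apply(sens[keep, , drop = FALSE], 1, function(s)
    sum(freqs * s) / sum(s))
  rownames(sens) <- paste0("dim", seq_len(nrow(sens)))
  new("TuningCurveSet", frequencies = freqs, sensitivity = sens,
      summaryHz = summ, cluster = factor(character()),
      excluded = as.integer(excluded))
}

#' Sensitivity-weighted mean frequency
#'
#' The tuning summary of a dimension: `sum(f * s(f)) / sum(s(f))`.
#'
#' @param curve numeric sensitivity vector over `frequencies`, or a
#'   [TuningCurveSet-class] (per-dimension summaries are returned).
#' @param frequencies Hz grid matching `curve` (vector form only).
#' @return Weighted mean frequency in Hz.
#' @export
tuningSummary <- function(curve, frequencies = NULL) {
  if (is(curve, "TuningCurveSet")) return(curve@summaryHz)
  if (is.null(frequencies)) stop("frequency grid required")
  sum(frequencies * curve) / sum(curve)
}

#' Cluster tuning summaries into low/high groups
#'
#' 1-D k-means (multiple restarts) over the weighted-mean frequencies; the
#' cluster with the smaller mean is labelled `low`.
#'
#' @param x a [TuningCurveSet-class] (clusters stored and returned in the
#'   object) or a numeric vector of summaries.
#' @param k number of clusters (default 2).
#' @param seed integer seed for the k-means restarts.
#' @return The updated [TuningCurveSet-class], or (vector form) a factor of
#'   `low`/`high` assignments.
#' @export
clusterTuning <- function(x, k = 2L, seed = 1L) {
  summaries <- if (is(x, "TuningCurveSet")) x@summaryHz else x
  ok <- which(!is.na(summaries))
  vals <- summaries[ok]
  if (length(unique(vals)) < k) {
    warning("degenerate tuning summaries: fewer distinct values than clusters")
    lab <- factor(rep("low", length(summaries)), levels = c("low", "high"))
  } else {
    km <- if (length(vals) == k)
      list(cluster = seq_len(k), centers = matrix(vals))  # one point each
    else
      withSeed(seed, kmeans(vals, centers = k, nstart = 25))
    ord <- order(km$centers)
    names <- c("low", "high", paste0("g", seq_len(max(0, k - 2)) + 2L))
    lev <- names[seq_len(k)]
    map <- character(k); map[ord] <- lev
    lab <- factor(rep(NA_character_, length(summaries)), levels = lev)
    lab[ok] <- map[km$cluster]
  }
  if (is(x, "TuningCurveSet")) initialize(x, cluster = lab) else lab
}

#' Bundled tactile-afferent reference curves
#'
#' Reads the packaged synthetic reference table of RA and PC afferent
#' frequency-sensitivity curves (normalized inverse discrimination
#' thresholds). The bundled table is a constructed stand-in consistent with
#' the canonical tuning bands (RA peak within 40--60 Hz, PC peak within
#' 250--300 Hz), not digitized physiological data; supply `path` to use
#' your own table (columns `curve`, `frequency_hz`, `sensitivity`).
#'
#' @param path optional CSV path overriding the bundled table.
#' @return data.frame with columns `curve`, `frequency_hz`, `sensitivity`.
#' @export
afferentReference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "afferent_reference_synthetic.csv",
                        package = "hapticAE", mustWork = TRUE)
  ref <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve", "frequency_hz", "sensitivity")
  if (!all(need %in% names(ref)))
    stop("reference table needs columns ", paste(need, collapse = ", "))
  ref
}

referencePeaks <- function(reference) {
  vapply(split(reference, reference$curve), function(d)
    d$frequency_hz[which.max(d$sensitivity)], 0)
}

#' Compare latent tuning clusters to afferent reference bands
#'
#' Computes each cluster's mean tuning curve and its peak frequency, then
#' matches clusters to the nearest reference curve peak. The comparison
#' passes qualitatively when the low cluster peaks nearer the RA band and
#' the high cluster nearer the PC band.
#'
#' @param curves a clustered [TuningCurveSet-class] (see [clusterTuning()]).
#' @param reference data.frame from [afferentReference()].
#' @return list with `clusterPeaks` (Hz per cluster), `referencePeaks`
#'   (Hz per afferent), `assignment` (cluster -> afferent),
#'   `bandDistance` (Hz per cluster) and `pass` (logical; NA when there is
#'   no bimodality to assess).
#' @export
compareToAfferents <- function(curves, reference = afferentReference()) {
  if (!length(curves@cluster) || all(is.na(curves@cluster)))
    stop("cluster the tuning summaries first (clusterTuning())")
  refPeaks <- referencePeaks(reference)
  lev <- levels(droplevels(curves@cluster))
  clusterPeaks <- vapply(lev, function(l) {
    rows <- which(curves@cluster == l)
    m <- colMeans(curves@sensitivity[rows, , drop = FALSE])
    curves@frequencies[which.max(m)]
  }, 0)
  assignment <- vapply(clusterPeaks, function(p)
    names(refPeaks)[which.min(abs(refPeaks - p))], "")
  bandDistance <- abs(clusterPeaks - refPeaks[assignment])
  pass <- if (length(lev) < 2) NA else
    identical(unname(assignment[c("low", "high")]), c("RA", "PC"))
  list(clusterPeaks = clusterPeaks, referencePeaks = refPeaks,
       assignment = assignment, bandDistance = bandDistance,
       pass = pass,
       note = if (length(lev) < 2) "single cluster: no bimodality" else NULL)
}
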