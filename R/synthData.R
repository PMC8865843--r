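# Simulation of vibratory recordings and rating tables.
#
# The generator emulates the study conditions the analysis pipeline assumes:
# 7 material categories with 81 material samples in total, 11 participants
# with uncontrolled exploration speed, category-specific spectral envelopes
# confined to the 10-800 Hz analysis band, sub-10 Hz hand-movement drift,
# broadband sensor noise above 800 Hz, and rating tables whose correlation
# structure reflects category membership.

ENVELOPE_FREQ <- seq(0, 1600, by = 2)

# evaluate a Gaussian-bump mixture envelope on the standard grid
bumpEnvelope <- function(centers, widths, amps, freq = ENVELOPE_FREQ) {
  env <- numeric(length(freq))
  for (i in seq_along(centers))
    env <- env + amps[i] * exp(-(freq - centers[i])^2 / (2 * widths[i]^2))
  env
}

drawBumps <- function(nBumps) {
  list(centers = runif(nBumps, 40, 650),
       widths  = runif(nBumps, 15, 80),
       amps    = runif(nBumps, 0.5, 1))
}

# smooth random frequency profiles used to map envelopes onto the seven
# latent haptic attributes that drive the rating simulator
attributeBasis <- function(freq, nAttr = 7L) {
  sapply(seq_len(nAttr), function(i) {
    b <- bumpEnvelope(runif(3, 20, 700), runif(3, 60, 200), rnorm(3))
    b - mean(b)
  })
}

#' Generate a synthetic material library
#'
#' Creates one material specification per sample: categories get distinct
#' base spectral envelopes (mixtures of 2-4 Gaussian bumps between 20 and
#' 700 Hz), and each material perturbs its category envelope by a small
#' multiplicative jitter on bump amplitudes and centres. A 7-dimensional
#' latent attribute vector per material is derived by projecting its
#' envelope onto smooth random frequency profiles, so perceived similarity
#' in the rating simulator tracks spectral similarity.
#'
#' @param nCategories number of categories (>= 2; default 7).
#' @param materialsPerCategory integer vector of per-category sample counts;
#'   the default `c(12, 12, 12, 12, 11, 11, 11)` sums to the canonical 81.
#' @param seed integer seed; the library is bit-reproducible given the seed.
#' @param jitterSD lognormal SD of the per-material bump-amplitude jitter.
#' @param centerJitterSD relative SD of the per-material bump-centre jitter.
#' @param mixMax upper bound of the per-material cross-category envelope
#'   mixing weight: each material blends its jittered category envelope
#'   with the base envelope of one random other category by a weight drawn
#'   uniformly from \[0, `mixMax`\]. This models samples whose physical
#'   make-up drifts toward another category (and which people may
#'   systematically perceive as that category); 0 disables it.
#' @param correlationCeiling categories are redrawn until all pairwise
#'   envelope correlations fall below this ceiling.
#' @return A [MaterialLibrary-class] object.
#' @examples
#' lib <- makeMaterialLibrary(seed = 1)
#' lib
#' @export
makeMaterialLibrary <- function(nCategories = 7L,
                                materialsPerCategory =
                                  c(12L, 12L, 12L, 12L, 11L, 11L, 11L),
                                seed = 1L,
                                jitterSD = 0.4,
                                centerJitterSD = 0.03,
                                mixMax = 0.8,
                                correlationCeiling = 0.8) {
  if (nCategories < 2L) stop("at least two categories required")
  if (length(materialsPerCategory) != nCategories)
    stop("one count per category required")
  if (any(materialsPerCategory <= 0))
    stop("material counts must be positive")
  withSeed(seed, {
    # draw category bump sets, redrawing offenders until envelopes are
    # pairwise distinct under the correlation ceiling
    bumps <- lapply(seq_len(nCategories),
                    function(i) drawBumps(sample(2:4, 1)))
    envs <- t(sapply(bumps, function(b)
      bumpEnvelope(b$centers, b$widths, b$amps)))
    for (try in seq_len(200)) {
      cc <- suppressWarnings(cor(t(envs)))
      diag(cc) <- 0
      bad <- which(apply(cc, 1, max) > correlationCeiling)
      if (!length(bad)) break
      for (i in bad) {
        bumps[[i]] <- drawBumps(sample(2:4, 1))
        envs[i, ] <- bumpEnvelope(bumps[[i]]$centers, bumps[[i]]$widths,
                                  bumps[[i]]$amps)
      }
    }
    cc <- suppressWarnings(cor(t(envs)))
    diag(cc) <- 0
    if (max(cc) > correlationCeiling)
      stop("could not draw sufficiently distinct category envelopes")

    total <- sum(materialsPerCategory)
    catId <- rep(seq_len(nCategories) - 1L, materialsPerCategory)
    matId <- sprintf("m%03d", seq_len(total))
    envMat <- matrix(0, total, length(ENVELOPE_FREQ))
    for (m in seq_len(total)) {
      b <- bumps[[catId[m] + 1L]]
      centers <- b$centers * (1 + rnorm(length(b$centers)) * centerJitterSD)
      amps <- b$amps * exp(rnorm(length(b$amps)) * jitterSD)
      own <- bumpEnvelope(centers, b$widths, amps)
      # blend toward one random other category's base envelope
      lambda <- if (nCategories > 1L && mixMax > 0) runif(1, 0, mixMax) else 0
      otherCat <- if (nCategories > 1L)
        sample(setdiff(seq_len(nCategories), catId[m] + 1L), 1L) else 1L
      envMat[m, ] <- (1 - lambda) * own + lambda * envs[otherCat, ]
    }
    rownames(envMat) <- matId
    rownames(envs) <- sprintf("c%d", seq_len(nCategories) - 1L)

    # attributes respond to the full envelope, level included — vibration
    # intensity co-determines percepts like roughness, and the latent codes
    # see it too
    basis <- attributeBasis(ENVELOPE_FREQ)
    attr <- envMat %*% basis
    attr <- scale(attr)
    attributes(attr)[c("scaled:center", "scaled:scale")] <- NULL
    rownames(attr) <- matId

    new("MaterialLibrary",
        materials = data.frame(material_id = matId, category_id = catId,
                               stringsAsFactors = FALSE),
        freq = ENVELOPE_FREQ, envelopes = envMat, categoryEnvelopes = envs,
        attributes = attr, seed = as.integer(seed))
  })
}

#' Generate the participant roster
#'
#' Eleven participants by default. Exploration speed was uncontrolled in the
#' emulated experiment, so each participant gets a multiplicative
#' `speed_factor` (log-uniform in \[0.8, 1.25\]) that scales the temporal
#' frequency content of their recordings, plus a rating-noise SD.
#'
#' @param nParticipants number of participants (default 11).
#' @param seed integer seed.
#' @param ratingNoiseSD common rating noise SD (default 0.8).
#' @return data.frame with columns `participant_id`, `speed_factor`,
#'   `rating_noise_sd`.
#' @export
makeParticipants <- function(nParticipants = 11L, seed = 1L,
                             ratingNoiseSD = 0.8) {
  withSeed(seed, {
    data.frame(
      participant_id = seq_len(nParticipants),
      speed_factor = exp(runif(nParticipants, log(0.8), log(1.25))),
      rating_noise_sd = rep(ratingNoiseSD, nParticipants))
  })
}

materialRow <- function(library, materialId) {
  i <- match(materialId, library@materials$material_id)
  if (is.na(i)) stop("unknown material: ", materialId)
  i
}

#' Simulate one vibratory recording
#'
#' Produces Gaussian noise spectrally shaped by the material envelope, with
#' the envelope scaled in frequency by the participant's exploration-speed
#' factor (a faster stroke shifts spectral content upward). A sub-10 Hz
#' hand-movement drift component and broadband sensor noise above 800 Hz are
#' added so the band-pass stage downstream has something real to remove.
#'
#' @param library a [MaterialLibrary-class].
#' @param materialId material to simulate.
#' @param participant one row of [makeParticipants()] output (or a list with
#'   `participant_id` and `speed_factor`).
#' @param durationS recording duration in seconds (default 10).
#' @param rateHz sampling rate in Hz (default 3200).
#' @param seed integer seed.
#' @param driftGain amplitude gain of the sub-10 Hz drift band.
#' @param noiseGain amplitude gain of the >800 Hz noise band.
#' @param floorGain amplitude gain of the broadband in-band (10--800 Hz)
#'   noise floor, emulating contact/sensor noise that band-pass filtering
#'   cannot remove; 0 disables it.
#' @return A [VibrationRecording-class] of `durationS * rateHz` samples.
#' @examples
#' lib <- makeMaterialLibrary(seed = 1)
#' pp <- makeParticipants(seed = 1)
#' rec <- synthRecording(lib, "m001", pp[1, ], durationS = 1, seed = 7)
#' @export
synthRecording <- function(library, materialId, participant,
                           durationS = 10, rateHz = 3200, seed = 1L,
                           driftGain = 0.6, noiseGain = 0.1,
                           floorGain = 0.35) {
  stopifnotScalar(durationS, "durationS", positive = TRUE)
  stopifnotScalar(rateHz, "rateHz", positive = TRUE)
  i <- materialRow(library, materialId)
  env <- library@envelopes[i, ]
  speed <- participant$speed_factor
  stopifnotScalar(speed, "speed_factor", positive = TRUE)
  # Nyquist guard on the (speed-scaled) envelope support
  support <- library@freq[env > 1e-6 * max(env, 1e-12)]
  fmax <- if (length(support)) max(support) * speed else 0
  if (rateHz <= 2 * fmax)
    stop(sprintf(
      "sampling rate %g Hz below Nyquist for envelope support up to %.0f Hz",
      rateHz, fmax))

  n <- round(durationS * rateHz)
  withSeed(seed, {
    f <- seq_len(n) - 1
    f <- pmin(f, n - f) * rateHz / n          # two-sided frequency axis
    # material gain, frequency axis compressed by the speed factor
    gain <- approx(library@freq, env, xout = f / speed, rule = 2,
                   yleft = 0, yright = 0)$y
    gain[f / speed > max(library@freq)] <- 0
    # sub-10 Hz hand-movement drift band, >800 Hz broadband noise, and an
    # in-band noise floor (contact/sensor noise inside the analysis band)
    drift <- driftGain * exp(-(f - 2)^2 / (2 * 2.5^2)) * (f < 10)
    hf <- noiseGain * (f > 850 & f < 1400)
    floor <- floorGain * (f >= 10 & f <= 800)
    gtot <- gain + drift + hf + floor
    x <- Re(fft(fft(rnorm(n)) * gtot, inverse = TRUE)) / n
    new("VibrationRecording", samples = x, rateHz = rateHz,
        participantId = as.integer(participant$participant_id),
        materialId = materialId,
        categoryId = library@materials$category_id[i])
  })
}

#' Simulate the rating experiment
#'
#' Descriptor ratings are a linear readout of each material's latent
#' attribute vector (shared within category up to the library's jitter)
#' plus participant rating noise. Category-similarity ratings are built from
#' the spectral similarity between the material's (jittered) envelope and
#' each category base envelope, plus a truth bonus that guarantees the true
#' category is rated highest in the noiseless, confusion-free limit. With
#' probability `confusion` a participant's similarity peak follows the
#' signal instead of the ground truth: it moves to the category whose base
#' envelope the material's own jittered envelope resembles most
#' (`confusionMode = "spectral"` — systematic across participants, and
#' visible to the autoencoder, so only genuinely drifted materials get
#' relabelled) or to a uniformly random category (`"uniform"`).
#'
#' @param library a [MaterialLibrary-class].
#' @param participants data.frame from [makeParticipants()].
#' @param seed integer seed.
#' @param confusion per-(participant, material) probability of a similarity
#'   peak displaced from the true category.
#' @param confusionMode `"spectral"` or `"uniform"`.
#' @param truthBonus additive similarity bonus for the true category.
#' @return A [RatingTable-class] with one descriptor row per
#'   (participant, material, descriptor) and one similarity row per
#'   (participant, material, category).
#' @export
synthRatings <- function(library, participants, seed = 1L,
                         confusion = 0.45,
                         confusionMode = c("spectral", "uniform"),
                         truthBonus = 1) {
  confusionMode <- match.arg(confusionMode)
  if (!nrow(library@materials) || !nrow(participants))
    stop("non-empty material and participant sets required")
  if (confusion < 0 || confusion > 1) stop("'confusion' must lie in [0, 1]")
  mats <- library@materials
  nMat <- nrow(mats); nPart <- nrow(participants)
  nCat <- nrow(library@categoryEnvelopes)
  catNames <- MATERIAL_CATEGORIES[seq_len(nCat)]

  # spectral similarity of each material to each category base envelope,
  # mapped from correlation to [0, 1]
  simBase <- suppressWarnings(
    cor(t(library@envelopes), t(library@categoryEnvelopes)))
  simBase <- (simBase + 1) / 2

  withSeed(seed, {
    desc <- vector("list", nPart)
    cats <- vector("list", nPart)
    for (p in seq_len(nPart)) {
      noiseSD <- participants$rating_noise_sd[p]
      vals <- library@attributes +
        matrix(rnorm(nMat * 7L, sd = noiseSD), nMat, 7L)
      desc[[p]] <- data.frame(
        participant_id = participants$participant_id[p],
        material_id = rep(mats$material_id, times = 7L),
        descriptor = rep(HAPTIC_DESCRIPTORS, each = nMat),
        value = as.vector(vals), stringsAsFactors = FALSE)

      sim <- simBase + matrix(rnorm(nMat * nCat, sd = noiseSD), nMat, nCat)
      lapse <- runif(nMat) < confusion
      for (m in seq_len(nMat)) {
        true <- mats$category_id[m] + 1L
        target <- true
        if (lapse[m]) {
          if (confusionMode == "uniform") {
            # an information-free lapse: the rating ignores the signal and
            # peaks at a uniformly random category
            target <- sample(seq_len(nCat), 1L)
            sim[m, ] <- rnorm(nCat, sd = noiseSD)
          } else {
            # a signal-driven lapse: the peak follows the category whose
            # base envelope the material's own (jittered, mixed) envelope
            # resembles most — drifted materials are relabelled to their
            # spectral neighbours consistently across participants
            target <- which.max(simBase[m, ])
          }
        }
        sim[m, target] <- sim[m, target] + truthBonus
      }
      cats[[p]] <- data.frame(
        participant_id = participants$participant_id[p],
        material_id = rep(mats$material_id, times = nCat),
        category = rep(catNames, each = nMat),
        similarity = as.vector(sim), stringsAsFactors = FALSE)
    }
    new("RatingTable",
        descriptors = do.call(rbind, desc),
        categories = do.call(rbind, cats),
        materials = mats, zTransformed = FALSE)
  })
}

#' Write a full recording set to disk
#'
#' Simulates one recording per (participant, material) and writes each trace
#' as a raw little-endian double array next to a `manifest.csv`
#' (`participant_id`, `material_id`, `category_id`, `path`, `rate_hz`,
#' `n_samples`).
#'
#' @inheritParams synthRecording
#' @param participants data.frame from [makeParticipants()].
#' @param dir output directory (created if missing).
#' @param seed master seed; per-recording seeds are derived from it.
#' @return Invisibly, the manifest data.frame.
#' @export
writeRecordingSet <- function(library, participants, dir,
                              durationS = 10, rateHz = 3200, seed = 1L,
                              driftGain = 0.6, noiseGain = 0.1,
                              floorGain = 0.35) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mats <- library@materials
  rows <- vector("list", nrow(mats) * nrow(participants))
  idx <- 0L
  for (p in seq_len(nrow(participants))) {
    for (m in seq_len(nrow(mats))) {
      idx <- idx + 1L
      rec <- synthRecording(library, mats$material_id[m],
                            participants[p, ], durationS, rateHz,
                            seed = childSeed(seed, idx),
                            driftGain = driftGain, noiseGain = noiseGain,
                            floorGain = floorGain)
      path <- file.path(dir, sprintf("rec_p%02d_%s.f64",
                                     rec@participantId, rec@materialId))
      con <- file(path, "wb")
      writeBin(rec@samples, con, size = 8, endian = "little")
      close(con)
      rows[[idx]] <- data.frame(
        participant_id = rec@participantId, material_id = rec@materialId,
        category_id = rec@categoryId, path = basename(path),
        rate_hz = rateHz, n_samples = length(rec@samples),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read one recording referenced by a manifest row
#'
#' @param dir directory holding the manifest and recordings.
#' @param manifestRow one row of the manifest data.frame.
#' @return A [VibrationRecording-class].
#' @export
readRecording <- function(dir, manifestRow) {
  path <- file.path(dir, manifestRow$path)
  con <- file(path, "rb")
  x <- readBin(con, "double", n = manifestRow$n_samples, size = 8,
               endian = "little")
  close(con)
  new("VibrationRecording", samples = x, rateHz = manifestRow$rate_hz,
      participantId = as.integer(manifestRow$participant_id),
      materialId = as.character(manifestRow$material_id),
      categoryId = as.integer(manifestRow$category_id))
}

#' Write rating tables as long-format CSV
#'
#' @param ratings a [RatingTable-class].
#' @param dir output directory.
#' @return Invisibly, the two file paths.
#' @export
writeRatings <- function(ratings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "ratings_descriptors.csv")
  p2 <- file.path(dir, "ratings_categories.csv")
  p3 <- file.path(dir, "materials.csv")
  write.csv(ratings@descriptors, p1, row.names = FALSE)
  write.csv(ratings@categories, p2, row.names = FALSE)
  write.csv(ratings@materials, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read rating tables written by [writeRatings()]
#'
#' @param dir directory holding the CSV files.
#' @return A [RatingTable-class] (not z-transformed).
#' @export
readRatings <- function(dir) {
  new("RatingTable",
      descriptors = read.csv(file.path(dir, "ratings_descriptors.csv"),
                             stringsAsFactors = FALSE),
      categories = read.csv(file.path(dir, "ratings_categories.csv"),
                            stringsAsFactors = FALSE),
      materials = read.csv(file.path(dir, "materials.csv"),
                           stringsAsFactors = FALSE),
      zTransformed = FALSE)
}

#' Ground-truth spectral distance matrix of the generator
#'
#' Category-by-category Euclidean distances between the mean realized
#' material envelopes of each category (jitter and cross-category mixing
#' included), i.e. the generator's own notion of how far apart the
#' categories actually are in the signals it produced.
#'
#' @param library a [MaterialLibrary-class].
#' @return A [DistanceMatrix-class] (latent flavour).
#' @export
envelopeDistanceMatrix <- function(library) {
  cats <- sort(unique(library@materials$category_id))
  e <- t(vapply(cats, function(cc)
    colMeans(library@envelopes[library@materials$category_id == cc, ,
                               drop = FALSE]),
    numeric(ncol(library@envelopes))))
  d <- as.matrix(dist(e))
  nCat <- nrow(e)
  dimnames(d) <- list(MATERIAL_CATEGORIES[seq_len(nCat)],
                      MATERIAL_CATEGORIES[seq_len(nCat)])
  new("DistanceMatrix", values = d, flavor = "latent")
}
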