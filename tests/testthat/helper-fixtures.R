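# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code under fixed seeds; nothing is read from
# disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# canonical 81-material / 7-category library
fixLibrary <- function() fixture("library", function() {
  makeMaterialLibrary(seed = 11)
})

fixParticipants <- function() fixture("participants", function() {
  makeParticipants(11, seed = 12)
})

# a reduced recording corpus: 3 participants x 81 materials, 2 s recordings
# (25 windows each) -> 6075 segments; enough category structure for the
# latent analyses at a fraction of the canonical data volume
fixSegments <- function() fixture("segments", function() {
  lib <- fixLibrary()
  pp <- makeParticipants(3, seed = 12)
  sets <- vector("list", 3 * nrow(lib@materials))
  idx <- 0L
  for (p in 1:3) {
    for (m in seq_len(nrow(lib@materials))) {
      idx <- idx + 1L
      rec <- synthRecording(lib, lib@materials$material_id[m], pp[p, ],
                            durationS = 2, rateHz = 3200, seed = idx)
      sets[[idx]] <- segmentRecording(bandpassFilter(rec), 80)
    }
  }
  all <- combineSegmentSets(sets)
  sp <- splitSegments(all, 0.95, seed = 13)
  train <- normalizeSegments(sp$train)
  k <- normalizationConstants(train)
  list(train = train,
       test = normalizeSegments(sp$test, k),
       full = normalizeSegments(all, k))
})

# one small trained model shared by tests that need a non-degenerate
# encoder; 4 epochs on a 2000-segment subsample keeps this quick
fixModel <- function() fixture("model", function() {
  segs <- fixSegments()
  keep <- sort(hapticAE:::withSeed(21, sample.int(nSegments(segs$train), 2000)))
  trainAutoencoder(buildAutoencoder(16), segs$train[, keep], segs$test,
                   epochs = 4, seed = 22)
})

fixRatings <- function() fixture("ratings", function() {
  synthRatings(fixLibrary(), fixParticipants(), seed = 15)
})

# well-separated Gaussian category clusters in 10-D: 81 materials over the
# canonical 7-category split
fixClusterEmbeddings <- function(sdWithin = 0.5, seed = 31,
                                 planar = FALSE) {
  sizes <- c(12L, 12L, 12L, 12L, 11L, 11L, 11L)
  labels <- rep(0:6, sizes)
  hapticAE:::withSeed(seed, {
    centers <- if (planar) {
      # cluster centres confined to a 2-D subspace with varied spacings,
      # so their geometry is representable by a 2-D map
      B <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
      matrix(rnorm(7 * 2, sd = 4), 7, 2) %*% t(B)
    } else matrix(rnorm(7 * 10, sd = 3), 7, 10)
    X <- centers[labels + 1L, ] + matrix(rnorm(81 * 10, sd = sdWithin), 81, 10)
  })
  rownames(X) <- sprintf("m%03d", seq_len(81))
  list(embeddings = X, labels = labels)
}
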