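test_that("material library has the canonical composition and is reproducible", {
  lib <- makeMaterialLibrary(seed = 5)
  expect_equal(nrow(lib@materials), 81L)
  expect_equal(length(unique(lib@materials$category_id)), 7L)
  expect_equal(as.vector(table(lib@materials$category_id)),
               c(12L, 12L, 12L, 12L, 11L, 11L, 11L))
  expect_true(all(lib@envelopes >= 0))
  # category envelopes mutually distinct under the correlation ceiling
  cc <- cor(t(lib@categoryEnvelopes))
  expect_true(max(cc[upper.tri(cc)]) < 0.8)
  # bit-reproducible
  lib2 <- makeMaterialLibrary(seed = 5)
  expect_identical(lib@envelopes, lib2@envelopes)
  expect_identical(lib@attributes, lib2@attributes)
  # minimal case
  tiny <- makeMaterialLibrary(2, c(1L, 1L), seed = 3)
  expect_equal(nrow(tiny@materials), 2L)
  expect_lt(cor(tiny@categoryEnvelopes[1, ], tiny@categoryEnvelopes[2, ]),
            0.8)
  expect_error(makeMaterialLibrary(2, c(0L, 2L), seed = 1), "positive")
})

test_that("synthetic recordings have the right length, spectrum and determinism", {
  lib <- fixLibrary()
  pp <- fixParticipants()
  rec <- synthRecording(lib, "m001", pp[1, ], durationS = 10,
                        rateHz = 3200, seed = 7)
  expect_length(rec@samples, 32000L)

  # speed factor scales the spectral peak: envelope pinned at 100 Hz,
  # speed 2 puts the empirical periodogram peak near 200 Hz
  lib2 <- makeMaterialLibrary(2, c(1L, 1L), seed = 5)
  lib2@envelopes[1, ] <- exp(-(lib2@freq - 100)^2 / (2 * 8^2))
  fast <- list(participant_id = 1L, speed_factor = 2)
  r <- synthRecording(lib2, "m001", fast, durationS = 2, rateHz = 3200,
                      seed = 3, driftGain = 0, noiseGain = 0, floorGain = 0)
  sp <- spec.pgram(ts(r@samples, frequency = 3200), plot = FALSE, spans = 15)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 200), 20)

  # null signal when every band amplitude is zero
  lib2@envelopes[1, ] <- 0
  z <- synthRecording(lib2, "m001", fast, durationS = 1, rateHz = 3200,
                      seed = 3, driftGain = 0, noiseGain = 0, floorGain = 0)
  expect_equal(max(abs(z@samples)), 0)

  # sub-Nyquist rate is rejected
  expect_error(synthRecording(lib, "m001", pp[1, ], durationS = 1,
                              rateHz = 500, seed = 1), "Nyquist")

  # determinism
  a <- synthRecording(lib, "m002", pp[2, ], durationS = 1, seed = 9)
  b <- synthRecording(lib, "m002", pp[2, ], durationS = 1, seed = 9)
  expect_identical(a@samples, b@samples)
})

test_that("recordings of one category are spectrally closer than across categories", {
  lib <- fixLibrary()
  pp <- fixParticipants()
  picks <- lib@materials[lib@materials$category_id %in% 0:2, ]
  picks <- do.call(rbind, lapply(split(picks, picks$category_id), head, 3))
  specs <- t(sapply(seq_len(nrow(picks)), function(i) {
    r <- synthRecording(lib, picks$material_id[i], pp[1, ], durationS = 1,
                        seed = 40 + i, driftGain = 0, noiseGain = 0,
                        floorGain = 0)
    spec.pgram(ts(r@samples, frequency = 3200), plot = FALSE,
               spans = 31)$spec
  }))
  cc <- cor(t(specs))
  same <- outer(picks$category_id, picks$category_id, "==")
  diag(same) <- NA
  expect_gt(mean(cc[which(same)]), mean(cc[which(!same)]))
})

test_that("rating tables have the documented shape and noise behaviour", {
  ratings <- fixRatings()
  expect_equal(nrow(ratings@descriptors), 11L * 81L * 7L)
  expect_equal(nrow(ratings@categories), 11L * 81L * 7L)

  # noiseless, confusion-free limit: every participant's top category is
  # the ground truth for every material
  lib <- fixLibrary()
  quiet <- makeParticipants(3, seed = 2, ratingNoiseSD = 0)
  r0 <- synthRatings(lib, quiet, seed = 1, confusion = 0)
  pl <- hapticAE:::participantLabels(r0)
  truth <- lib@materials$category_id[match(pl$material_id,
                                           lib@materials$material_id)]
  expect_true(all(pl$label == truth))

  # uniform total confusion: majority-vote label accuracy near chance (1/7)
  accs <- sapply(1:5, function(s) {
    r1 <- synthRatings(lib, makeParticipants(11, seed = s), seed = s,
                       confusion = 1, confusionMode = "uniform")
    lab <- assignPerceptualLabels(r1)
    mean(lab$perceptual_label == lab$ground_truth)
  })
  expect_gt(mean(accs), 1 / 7 - 0.06)
  expect_lt(mean(accs), 1 / 7 + 0.06)
})

test_that("recording sets round-trip through the manifest container", {
  lib <- makeMaterialLibrary(2, c(2L, 2L), seed = 8)
  pp <- makeParticipants(2, seed = 8)
  dir <- withr::local_tempdir()
  manifest <- writeRecordingSet(lib, pp, dir, durationS = 0.4, seed = 6)
  expect_equal(nrow(manifest), 8L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  rec <- readRecording(dir, manifest[3, ])
  expect_s4_class(rec, "VibrationRecording")
  expect_length(rec@samples, 1280L)
  # identical to the in-memory generation under the derived seed
  direct <- synthRecording(lib, manifest$material_id[3],
                           pp[pp$participant_id ==
                                manifest$participant_id[3], ],
                           durationS = 0.4, seed = hapticAE:::childSeed(6, 3))
  expect_equal(rec@samples, direct@samples)
})
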