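test_that("architecture realizes the canonical layer schedule", {
  spec <- buildAutoencoder(16)
  sh <- autoencoderShapes(spec)
  # encoder time schedule 256 -> 64 -> 16 -> 4 -> 1 via factor-4 pooling,
  # decoder mirror 1 -> 4 -> 16 -> 64 -> 256
  expect_equal(sh$timeIn, c(256L, 64L, 16L, 4L, 1L, 4L, 16L, 64L, 256L))
  expect_equal(sh$featOut, c(64L, 32L, 16L, 16L, 16L, 16L, 32L, 64L, 1L))
  expect_equal(sh$featIn, c(1L, 64L, 32L, 16L, 16L, 16L, 16L, 32L, 64L))
  # realized parameter shapes match the schedule (kernel 5)
  w <- hapticAE:::initWeights(spec, seed = 1)
  expect_equal(vapply(w, function(l) nrow(l$W), 0L), sh$featOut)
  expect_equal(vapply(w, function(l) ncol(l$W), 0L), sh$featIn * 5L)

  # wider bottlenecks clamp every feature count to >= latentDim
  spec256 <- buildAutoencoder(256)
  expect_true(all(spec256@encoderFeatures >= 256L))
  expect_true(all(spec256@decoderFeatures[-5] >= 256L))
  expect_error(buildAutoencoder(0), "1..256")
  expect_error(buildAutoencoder(300), "1..256")
})

test_that("compression rate follows the latent/input ratio in percent", {
  expect_equal(compressionRate(16), 6.25)
  expect_equal(compressionRate(256), 100)
  expect_equal(compressionRate(64), 25)
  expect_error(compressionRate(0), "positive")
})

test_that("training reduces MAE, converges on constant targets, is deterministic", {
  meta <- data.frame(participant_id = 1L, material_id = "m001",
                     category_id = 0L, segment_index = 1:64)
  segs <- SegmentSet(matrix(0.5, 256, 64), meta, 3200)
  spec <- buildAutoencoder(16)
  m <- trainAutoencoder(spec, segs, epochs = 25, batchSize = 16, seed = 1)
  rep <- trainingReport(m)
  # optimization sanity and the closed-form optimum for a constant target
  expect_lte(rep$trainMAE[25], rep$trainMAE[1])
  expect_lt(rep$trainMAE[25], 1e-3)
  recon <- segmentData(reconstructSegments(m, segs))
  expect_lt(max(abs(recon - 0.5)), 0.01)
  # reconstructions stay strictly inside the sigmoid range
  expect_true(all(recon > 0 & recon < 1))
  # identical seed, identical loss curve
  m2 <- trainAutoencoder(spec, segs, epochs = 25, batchSize = 16, seed = 1)
  expect_identical(trainingReport(m), trainingReport(m2))
  # un-normalized input is rejected
  bad <- SegmentSet(matrix(rnorm(256 * 4), 256, 4), meta[1:4, ], 3200)
  expect_error(trainAutoencoder(spec, bad), "normalized")
})

test_that("encoding yields the code shape contract and functional determinism", {
  model <- fixModel()
  segs <- fixSegments()$test
  codes <- encodeSegments(model, segs[, 1:8])
  expect_equal(dim(SummarizedExperiment::assay(codes, "code")),
               c(16L, 8L))
  # duplicated segment -> identical code
  dup <- segs[, c(1, 1)]
  cd <- SummarizedExperiment::assay(encodeSegments(model, dup), "code")
  expect_identical(cd[, 1], cd[, 2])
  # all-zero vs all-one inputs produce distinct codes for a trained model
  meta <- data.frame(participant_id = 1L, material_id = "m001",
                     category_id = 0L, segment_index = 1:2)
  extremes <- SegmentSet(cbind(rep(0, 256), rep(1, 256)), meta, 3200)
  ce <- SummarizedExperiment::assay(encodeSegments(model, extremes), "code")
  expect_gt(max(abs(ce[, 1] - ce[, 2])), 1e-6)
  expect_error(encodeSegments(model,
    SegmentSet(matrix(0.5, 128, 2), meta, 3200)), "256")
})

test_that("per-segment R2 matches a brute-force oracle and its documented quirks", {
  x <- cbind(c(1, 2, 3, 5), c(2, 1, 4, 4), c(0, 1, 0, 1))
  y <- cbind(c(1.1, 2.2, 2.9, 4.7), c(2, 2, 3, 5), c(1, 0, 1, 0))
  # independent brute force from the correlation formula
  brute <- mean(sapply(1:3, function(i) {
    xi <- x[, i]; yi <- y[, i]
    (sum((xi - mean(xi)) * (yi - mean(yi))) /
       sqrt(sum((xi - mean(xi))^2) * sum((yi - mean(yi))^2)))^2
  }))
  expect_equal(hapticAE:::segmentR2(x, y), brute, tolerance = 1e-12)
  # perfect reconstruction and the r^2 sign-invariance property
  expect_equal(hapticAE:::segmentR2(x, x), 1)
  expect_equal(hapticAE:::segmentR2(x, -x + 1), 1)
  # constant segments are excluded with a warning
  xc <- x; xc[, 2] <- 7
  expect_warning(r2 <- hapticAE:::segmentR2(xc, y), "constant")
  expect_equal(r2, mean(sapply(c(1, 3), function(i)
    cor(x[, i], y[, i])^2)), tolerance = 1e-12)
})
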