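test_that("sinusoid bank has the canonical grid, offset and phase structure", {
  bank <- makeSinusoidBank()
  cd <- SummarizedExperiment::colData(bank)
  freqs <- sort(unique(cd$frequency))
  expect_length(freqs, 829L)  # 830 grid points, 0 Hz folded into the first
  expect_equal(diff(freqs)[1], 800 / 829, tolerance = 1e-9)
  expect_equal(max(freqs), 800)
  expect_equal(nSegments(bank), 830L * 8L)
  d <- segmentData(bank)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(mean(d), 0.5, tolerance = 1e-3)
  # f = rate/4 gives exactly 64 cycles in 256 samples
  tt <- (0:255) / 3200
  s <- sin(2 * pi * 800 * tt)
  expect_equal(sum(abs(diff(sign(s)) != 0)), 2 * 64)
  # zero amplitude: constant mid-range signals
  flat <- makeSinusoidBank(n = 5, amplitude = 0, nPhases = 2)
  expect_equal(range(segmentData(flat)), c(0.5, 0.5))
  expect_error(makeSinusoidBank(amplitude = 0.7), "overflow")
  expect_error(makeSinusoidBank(fMax = 2000), "Nyquist")
})

test_that("probe recovers the analytic response of a linear band-pass encoder", {
  # single-unit linear encoder: inner product with a 150 Hz Gabor filter
  tt <- (0:255) / 3200
  h <- sin(2 * pi * 150 * tt) * exp(-((tt - 0.04) / 0.02)^2)
  enc <- function(X) matrix(crossprod(X, h), ncol = 1)
  bank <- makeSinusoidBank(n = 415, nPhases = 8)
  curves <- probeTuning(enc, NULL, bank)
  freqs <- curves@frequencies
  peak <- freqs[which.max(curves@sensitivity[1, ])]
  expect_lt(abs(peak - 150), 10)
  # full-curve oracle equivalence: |H(f)| from the DFT of the filter
  H <- abs(fft(c(h, rep(0, 4096 - 256))))
  fH <- (0:4095) * 3200 / 4096
  analytic <- approx(fH[1:2048], H[1:2048], xout = freqs)$y
  analytic <- (analytic - min(analytic)) / diff(range(analytic))
  expect_gt(cor(analytic, curves@sensitivity[1, ]), 0.995)
  expect_lt(max(abs(analytic - curves@sensitivity[1, ])), 0.08)

  # identical model probed twice gives identical curves
  curves2 <- probeTuning(enc, NULL, bank)
  expect_identical(curves@sensitivity, curves2@sensitivity)

  # identity (sample-reading) encoder: near-uniform sensitivity, so the
  # weighted-mean summary sits near the grid midpoint for every unit
  encId <- function(X) t(X[2:5, , drop = FALSE])
  flatCurves <- probeTuning(encId, NULL, bank)
  expect_true(all(abs(flatCurves@summaryHz - 400) < 40))
})

test_that("tuning summary is the sensitivity-weighted mean frequency", {
  f <- seq(0, 800, by = 100)
  s <- rep(0, 9); s[4] <- 1  # concentrated at 300 Hz
  expect_equal(tuningSummary(s, f), 300)
  expect_equal(tuningSummary(rep(1, 9), f), 400)  # uniform -> midpoint
  twoPeaks <- rep(0, 9); twoPeaks[f == 100] <- 1; twoPeaks[f == 300] <- 1
  expect_equal(tuningSummary(twoPeaks, f), 200)
})

test_that("1-D k-means splits summaries into ordered low/high groups", {
  lab <- clusterTuning(c(50, 55, 260, 270), seed = 2)
  expect_equal(as.character(lab), c("low", "low", "high", "high"))
  # exhaustive 1-D oracle: best 2-partition of sorted values by total
  # within-cluster sum of squares
  vals <- c(30, 45, 90, 240, 280, 310)
  best <- which.min(sapply(1:5, function(cut) {
    a <- vals[1:cut]; b <- vals[-(1:cut)]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }))
  oracle <- rep(c("low", "high"), c(best, length(vals) - best))
  expect_equal(as.character(clusterTuning(vals, seed = 2)), oracle)
  # permutation invariance of the grouping
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(as.character(clusterTuning(vals[perm], seed = 2)),
               oracle[perm])
  expect_warning(flat <- clusterTuning(rep(100, 4), seed = 1), "degenerate")
})

test_that("cluster peaks map onto the afferent reference bands", {
  ref <- afferentReference()
  expect_setequal(unique(ref$curve), c("RA", "PC"))
  peaks <- hapticAE:::referencePeaks(ref)
  expect_true(peaks["RA"] >= 40 && peaks["RA"] <= 60)
  expect_true(peaks["PC"] >= 250 && peaks["PC"] <= 300)
  expect_true(all(ref$sensitivity >= 0 & ref$sensitivity <= 1))

  # curves equal to the references themselves: zero band distance
  grid <- sort(unique(ref$frequency_hz))
  sens <- rbind(
    approx(ref$frequency_hz[ref$curve == "RA"],
           ref$sensitivity[ref$curve == "RA"], grid)$y,
    approx(ref$frequency_hz[ref$curve == "PC"],
           ref$sensitivity[ref$curve == "PC"], grid)$y)
  sens <- t(apply(sens, 1, function(v) (v - min(v)) / diff(range(v))))
  rownames(sens) <- c("dim1", "dim2")
  tcs <- new("TuningCurveSet", frequencies = grid, sensitivity = sens,
             summaryHz = apply(sens, 1, function(s) sum(grid * s) / sum(s)),
             cluster = factor(character()), excluded = integer())
  tcs <- clusterTuning(tcs, seed = 3)
  cmp <- compareToAfferents(tcs)
  expect_equal(unname(cmp$bandDistance), c(0, 0))
  expect_true(cmp$pass)

  # synthetic low/high clusters at 50 and 275 Hz map low->RA, high->PC
  f <- seq(5, 800, by = 5)
  mk <- function(mu) exp(-(log(f / mu))^2 / (2 * 0.4^2))
  sens2 <- rbind(mk(50), mk(52), mk(275), mk(280))
  sens2 <- t(apply(sens2, 1, function(v) (v - min(v)) / diff(range(v))))
  rownames(sens2) <- paste0("dim", 1:4)
  tcs2 <- new("TuningCurveSet", frequencies = f, sensitivity = sens2,
              summaryHz = apply(sens2, 1, function(s) sum(f * s) / sum(s)),
              cluster = factor(character()), excluded = integer())
  tcs2 <- clusterTuning(tcs2, seed = 4)
  cmp2 <- compareToAfferents(tcs2)
  expect_equal(unname(cmp2$assignment[c("low", "high")]), c("RA", "PC"))
  expect_true(cmp2$pass)
})
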