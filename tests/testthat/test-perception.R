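# build a minimal rating table directly (3 materials, 2 categories would
# violate the 7-category contract, so synthetic tables come from the
# generator; hand-built tables below keep 7 descriptors/categories)
mkRatingTable <- function(desc, cats, materials) {
  new("RatingTable", descriptors = desc, categories = cats,
      materials = materials, zTransformed = FALSE)
}

test_that("z-transform standardizes each (participant, descriptor) slice", {
  ratings <- fixRatings()
  z <- zTransform(ratings)
  expect_true(z@zTransformed)
  d <- z@descriptors
  for (p in unique(d$participant_id)[1:3]) {
    for (dsc in HAPTIC_DESCRIPTORS[c(1, 4)]) {
      v <- d$value[d$participant_id == p & d$descriptor == dsc]
      expect_equal(mean(v), 0, tolerance = 1e-10)
      expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-10)
    }
  }
  # population-SD convention: [1,2,3] -> +-1.224745
  x <- c(1, 2, 3)
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(zx, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # idempotence
  z2 <- zTransform(z)
  expect_equal(z2@descriptors$value, z@descriptors$value, tolerance = 1e-9)
  # zero-variance slice is rejected with the offender named
  bad <- ratings
  i <- bad@descriptors$participant_id == 1 &
    bad@descriptors$descriptor == "hardness"
  bad@descriptors$value[i] <- 3
  expect_error(zTransform(bad), "participant 1.*hardness")
})

test_that("ratings PCA bookkeeping matches constructed ranks", {
  ratings <- zTransform(fixRatings())
  pca <- ratingsPCA(ratings)
  evr <- explainedVariance(pca)
  expect_equal(sum(evr), 1, tolerance = 1e-9)
  expect_true(all(diff(evr) <= 1e-12))
  expect_error(ratingsPCA(fixRatings()), "z-transform")

  # rank-2 ratings: first two components explain everything
  lib <- fixLibrary()
  rank2 <- lib
  set.seed(8)
  A <- matrix(rnorm(81 * 2), 81, 2)
  rank2@attributes <- A %*% matrix(rnorm(14), 2, 7)
  r <- zTransform(synthRatings(rank2, makeParticipants(3, seed = 2,
                                                       ratingNoiseSD = 0),
                               seed = 3, confusion = 0))
  evr2 <- explainedVariance(ratingsPCA(r))
  expect_gt(sum(evr2[1:2]), 0.999)
})

test_that("perceptual distances follow delta = 2(1 - rho) with a sqrt variant", {
  # endpoints of the distance map
  expect_equal(2 * (1 - 1), 0)
  ratings <- zTransform(fixRatings())
  dm <- perceptualDistanceMatrix(ratings)
  v <- distanceValues(dm)
  expect_equal(v, t(v))
  expect_equal(dim(v), c(7L, 7L))
  # rho in [-1, 1] bounds delta in [0, 4] as printed; sqrt variant in [0, 2]
  expect_true(all(v >= 0 & v <= 4))
  vs <- distanceValues(perceptualDistanceMatrix(ratings, method = "sqrt"))
  expect_equal(vs, sqrt(v), tolerance = 1e-12)
  # delta strictly decreasing in rho
  rho <- seq(-1, 1, 0.25)
  expect_true(all(diff(2 * (1 - rho)) < 0))

  # brute-force oracle on a small instance: recompute category-pair
  # correlations directly from the pooled material vectors
  m <- hapticAE:::pooledDescriptorMatrix(ratings)
  cats <- ratings@materials$category_id[
    match(rownames(m), ratings@materials$material_id)]
  a <- which(cats == 0); b <- which(cats == 1)
  rhoAB <- mean(outer(a, b, Vectorize(function(i, j)
    cor(m[i, ], m[j, ]))))
  expect_equal(v[1, 2], 2 * (1 - rhoAB), tolerance = 1e-10)
  # diagonal: distinct within-category pairs only
  pairsA <- combn(a, 2)
  rhoAA <- mean(apply(pairsA, 2, function(ij) cor(m[ij[1], ], m[ij[2], ])))
  expect_equal(v[1, 1], 2 * (1 - rhoAA), tolerance = 1e-10)
})

test_that("perceptual labels recover ground truth in the noiseless limit", {
  lib <- fixLibrary()
  quiet <- makeParticipants(11, seed = 3, ratingNoiseSD = 0)
  r <- synthRatings(lib, quiet, seed = 4, confusion = 0)
  lab <- assignPerceptualLabels(r)
  expect_equal(lab$perceptual_label, lab$ground_truth)
  expect_true(all(lab$vote_count == 11L))
})

test_that("majority voting follows the documented 6-vs-5 and tie rules", {
  expect_equal(hapticAE:::majorityVote(c(rep(2L, 6), rep(5L, 5))), 2L)
  # tie: lowest category index wins
  expect_equal(hapticAE:::majorityVote(c(rep(4L, 5), rep(1L, 5), 6L)), 1L)
})

test_that("agreement level behaves at the documented extremes", {
  lib <- fixLibrary()
  # no noise, no confusion: all participants agree -> 100%
  r <- synthRatings(lib, makeParticipants(5, seed = 3, ratingNoiseSD = 0),
                    seed = 4, confusion = 0)
  expect_equal(agreementLevel(r), 100)
  # independent-uniform labels: agreement near chance (1/7)
  accs <- sapply(1:4, function(s) {
    ru <- synthRatings(lib, makeParticipants(11, seed = s,
                                             ratingNoiseSD = 0),
                       seed = 10 + s, confusion = 1,
                       confusionMode = "uniform")
    agreementLevel(ru)
  })
  expect_lt(abs(mean(accs) - 100 / 7), 5)
  # two participants: prediction is exactly the other participant's label
  r2 <- synthRatings(lib, makeParticipants(2, seed = 6), seed = 7,
                     confusion = 0.3)
  pl <- hapticAE:::participantLabels(r2)
  w <- reshape(pl, direction = "wide", idvar = "material_id",
               timevar = "participant_id")
  manual <- 100 * mean(c(w[[2]] == w[[3]], w[[3]] == w[[2]]))
  expect_equal(agreementLevel(r2), manual)
})
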