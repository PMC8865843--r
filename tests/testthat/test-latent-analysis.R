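mkCodes <- function(X, materials = NULL, categories = NULL) {
  n <- nrow(X)
  if (is.null(materials)) materials <- sprintf("m%03d", seq_len(n))
  if (is.null(categories)) categories <- rep(0L, n)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(code = t(X)),
    colData = S4Vectors::DataFrame(
      participant_id = 1L, material_id = materials,
      category_id = categories, segment_index = seq_len(n)))
}

test_that("latent PCA picks the minimal dimensionality reaching the threshold", {
  # rank-3 codes: exactly 3 non-trivial directions
  set.seed(4)
  B <- matrix(rnorm(16 * 3), 3, 16)
  X <- matrix(rnorm(200 * 3), 200, 3) %*% B
  pcs <- fitLatentPCA(mkCodes(X), 0.95)
  expect_equal(retainedDim(pcs), 3L)
  # isotropic 16-D codes: every component carries ~1/16, k hits 16
  iso <- fitLatentPCA(mkCodes(matrix(rnorm(4000 * 16), 4000, 16)), 0.95)
  expect_equal(retainedDim(iso), 16L)
  expect_lt(max(abs(explainedVariance(iso) - 1 / 16)), 0.01)
  # definition of k: cumulative variance crosses the threshold exactly at k
  segs <- fixSegments()
  codes <- encodeSegments(fixModel(), segs$full)
  pcs2 <- fitLatentPCA(codes, 0.95)
  cum <- cumsum(explainedVariance(pcs2))
  k <- retainedDim(pcs2)
  expect_gte(cum[k], 0.95)
  if (k > 1) expect_lt(cum[k - 1], 0.95)
  # conservation: ratios sum to 1, non-increasing, non-negative
  evr <- explainedVariance(pcs2)
  expect_equal(sum(evr), 1, tolerance = 1e-9)
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0))
  expect_error(fitLatentPCA(mkCodes(X), 1.5), "lie in")
})

test_that("PCA projection is lossless from all components", {
  set.seed(5)
  X <- matrix(rnorm(60 * 16), 60, 16)
  pcs <- fitLatentPCA(mkCodes(X), 1)
  back <- pcs@projected %*% t(pcs@rotation[, seq_len(pcs@k)])
  back <- sweep(back, 2, pcs@center, "+")
  expect_equal(unname(back), X, tolerance = 1e-10)
})

test_that("material embeddings average segment projections per material", {
  set.seed(6)
  X <- matrix(rnorm(90 * 8), 90, 8)
  mats <- rep(sprintf("m%03d", 1:9), each = 10)
  cats <- rep(0:2, each = 30)
  pcs <- fitLatentPCA(mkCodes(X, mats, cats), 0.999)
  emb <- materialEmbeddings(pcs)
  expect_equal(ncol(emb), 9L)
  # arithmetic oracle on one material
  i <- which(mats == "m003")
  expect_equal(
    unname(SummarizedExperiment::assay(emb)[, 3]),
    unname(colMeans(pcs@projected[i, ])), tolerance = 1e-12)
  # a material whose segments are identical embeds at that projection
  X2 <- X; X2[1:10, ] <- rep(X[1, ], each = 10)
  pcs2 <- fitLatentPCA(mkCodes(X2, mats, cats), 0.999)
  expect_equal(unname(SummarizedExperiment::assay(materialEmbeddings(pcs2))[, 1]),
               unname(pcs2@projected[1, ]), tolerance = 1e-10)
  expect_error(materialEmbeddings(pcs, materials = c("m001", "zz")), "zz")
})

test_that("category centroids and their distance matrix obey coordinate geometry", {
  emb <- rbind(c(0, 0), c(2, 0), c(0, 0), c(0, 4), c(3, 4), c(3, 0))
  labels <- c(0L, 0L, 1L, 1L, 2L, 2L)
  cent <- categoryCentroids(emb, labels)
  expect_equal(unname(cent), rbind(c(1, 0), c(0, 2), c(3, 2)))
  # singleton category: centroid equals the point
  cent1 <- categoryCentroids(matrix(c(5, 7), 1), 0L)
  expect_equal(unname(cent1), matrix(c(5, 7), 1))
  # permuting material order leaves centroids unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(categoryCentroids(emb[perm, ], labels[perm]), cent)
  dm <- centroidDistanceMatrix(cent)
  v <- distanceValues(dm)
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(0, 3))
  expect_equal(v[1, 2], sqrt(1 + 4))  # hand-computed Euclidean distance
  # identical centroids give an all-zero matrix
  expect_equal(max(distanceValues(centroidDistanceMatrix(
    rbind(c(1, 1), c(1, 1))))), 0)
})

test_that("distance-matrix correlation uses the 21 upper-triangle pairs", {
  set.seed(7)
  v <- matrix(rnorm(49), 7); v <- abs(v + t(v)); diag(v) <- 0
  dimnames(v) <- list(MATERIAL_CATEGORIES, MATERIAL_CATEGORIES)
  a <- new("DistanceMatrix", values = v, flavor = "latent")
  expect_equal(matrixCorrelation(a, a), 1)
  # affine invariance of Pearson r
  b <- new("DistanceMatrix", values = 2 * v + 3, flavor = "perceptual")
  expect_equal(matrixCorrelation(a, b), 1)
  # 3x3 hand-entered oracle
  m1 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  m2 <- matrix(c(0, 2, 1, 2, 0, 5, 1, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  d1 <- new("DistanceMatrix", values = m1, flavor = "latent")
  d2 <- new("DistanceMatrix", values = m2, flavor = "latent")
  # upper triangles are (1,2,3) and (2,1,5); direct formula
  expect_equal(matrixCorrelation(d1, d2), cor(c(1, 2, 3), c(2, 1, 5)))
  bad <- new("DistanceMatrix",
             values = matrix(0, 3, 3,
                             dimnames = list(letters[4:6], letters[4:6])),
             flavor = "latent")
  expect_error(matrixCorrelation(d1, bad), "labels")
})

test_that("latent machinery recovers generator geometry from an informative encoding", {
  # encode every window by log band energies — an analytically informative
  # stand-in representation — and check that the PCA / embedding /
  # centroid / distance chain recovers the generator's category geometry
  segs <- fixSegments()
  lib <- fixLibrary()
  bandEncoder <- function(X) {
    n <- nrow(X)
    f <- (0:(n - 1)) * 3200 / n
    P <- abs(mvfft(X - matrix(colMeans(X), n, ncol(X), byrow = TRUE)))^2
    edges <- seq(10, 810, 100)
    t(vapply(seq_len(8), function(b)
      log(colSums(P[f >= edges[b] & f < edges[b + 1], , drop = FALSE]) +
            1e-9), numeric(ncol(X))))
  }
  codes <- SummarizedExperiment::SummarizedExperiment(
    assays = list(code = bandEncoder(segmentData(segs$full))),
    colData = SummarizedExperiment::colData(segs$full))
  pcs <- fitLatentPCA(codes, 0.95)
  emb <- materialEmbeddings(pcs)
  latD <- centroidDistanceMatrix(categoryCentroids(emb))
  expect_gt(matrixCorrelation(latD, envelopeDistanceMatrix(lib)), 0.5)
})

test_that("t-SNE map is reproducible and preserves separated cluster geometry", {
  fx <- fixClusterEmbeddings(sdWithin = 2, seed = 41, planar = TRUE)
  emb <- SummarizedExperiment::SummarizedExperiment(
    assays = list(embedding = t(fx$embeddings)),
    colData = S4Vectors::DataFrame(
      material_id = rownames(fx$embeddings), category_id = fx$labels))
  y1 <- tsneEmbed(emb, seed = 3, perplexity = 20, maxIter = 600)
  y2 <- tsneEmbed(emb, seed = 3, perplexity = 20, maxIter = 600)
  expect_identical(y1, y2)
  # well-separated clusters: 2-D vs 10-D centroid distances correlate > 0.9
  expect_gt(tsneFidelity(y1, emb), 0.9)
  # duplicate inputs land on near-coincident points
  X <- fx$embeddings; X[2, ] <- X[1, ]
  emb2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(embedding = t(X)),
    colData = S4Vectors::DataFrame(
      material_id = rownames(X), category_id = fx$labels))
  y3 <- tsneEmbed(emb2, seed = 3, perplexity = 20, maxIter = 600)
  d12 <- sqrt(sum((y3[1, ] - y3[2, ])^2))
  others <- as.matrix(dist(y3))
  expect_lt(d12, quantile(others[others > 0], 0.01))
  expect_error(tsneEmbed(emb, perplexity = 81), "perplexity")
})
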