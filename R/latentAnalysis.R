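# Latent-space analyses: PCA, per-material embeddings, category centroids,
# distance matrices, t-SNE view and distance-matrix correlation.

#' Principal components of the latent codes
#'
#' Fits a PCA on the latent codes of the full data set (centred, unscaled)
#' and retains the smallest number of components `k` whose cumulative
#' explained variance reaches `varianceThreshold` (the canonical analysis
#' space retains 95\% of variance).
#'
#' @param codes a `SummarizedExperiment` from [encodeSegments()]
#'   (`latentDim x N` code assay) or a plain matrix (N x d).
#' @param varianceThreshold cumulative explained-variance target in (0, 1].
#' @return A [LatentPCSpace-class].
#' @export
fitLatentPCA <- function(codes, varianceThreshold = 0.95) {
  if (!(varianceThreshold > 0 && varianceThreshold <= 1))
    stop("'varianceThreshold' must lie in (0, 1]")
  if (is(codes, "SummarizedExperiment")) {
    X <- t(SummarizedExperiment::assay(codes, "code"))
    info <- SummarizedExperiment::colData(codes)
  } else {
    X <- as.matrix(codes)
    info <- S4Vectors::DataFrame(row = seq_len(nrow(X)))
  }
  if (nrow(X) <= ncol(X))
    stop("need more code points than latent dimensions")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(evr) >= varianceThreshold - 1e-12)[1]
  new("LatentPCSpace",
      rotation = pc$rotation, center = pc$center, evr = evr,
      k = as.integer(k), threshold = varianceThreshold,
      projected = pc$x[, seq_len(k), drop = FALSE],
      segmentInfo = info)
}

#' Project new codes into a fitted PC space
#'
#' @param pcspace a [LatentPCSpace-class].
#' @param codes matrix (N x d) or code `SummarizedExperiment`.
#' @return Matrix (N x k) of projections.
#' @export
projectCodes <- function(pcspace, codes) {
  X <- if (is(codes, "SummarizedExperiment"))
    t(SummarizedExperiment::assay(codes, "code")) else as.matrix(codes)
  sweep(X, 2, pcspace@center) %*%
    pcspace@rotation[, seq_len(pcspace@k), drop = FALSE]
}

#' Per-material embeddings
#'
#' Averages the projected latent representations of all segments of each
#' material, yielding one point per material sample in the latent PCs
#' space.
#'
#' @param pcspace a [LatentPCSpace-class] whose segment metadata carries
#'   `material_id` and `category_id`.
#' @param materials optional character vector of material ids that must all
#'   be present; a material without segments raises an error naming it.
#' @return A `SummarizedExperiment` with a `k x nMaterials` `embedding`
#'   assay and per-material `colData` (`material_id`, `category_id`).
#' @export
materialEmbeddings <- function(pcspace, materials = NULL) {
  info <- as.data.frame(pcspace@segmentInfo)
  if (!all(c("material_id", "category_id") %in% names(info)))
    stop("segment metadata must carry material_id and category_id")
  if (!is.null(materials)) {
    missing <- setdiff(materials, info$material_id)
    if (length(missing))
      stop("material(s) without segments: ", paste(missing, collapse = ", "))
  }
  ids <- sort(unique(info$material_id))
  emb <- matrix(vapply(ids, function(m)
    colMeans(pcspace@projected[info$material_id == m, , drop = FALSE]),
    numeric(pcspace@k)), nrow = pcspace@k)
  cats <- vapply(ids, function(m)
    info$category_id[match(m, info$material_id)], 0L)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(embedding = emb),
    colData = S4Vectors::DataFrame(material_id = ids, category_id = cats))
}

embeddingMatrix <- function(embeddings) {
  t(SummarizedExperiment::assay(embeddings, "embedding"))
}

embeddingCategories <- function(embeddings) {
  SummarizedExperiment::colData(embeddings)$category_id
}

#' Category centroids in the latent PCs space
#'
#' @param embeddings `SummarizedExperiment` from [materialEmbeddings()], or
#'   a matrix (materials x k) if `labels` is given.
#' @param labels category labels per material (ignored for the
#'   SummarizedExperiment form).
#' @return Matrix (categories x k) of centroid coordinates, rownames are
#'   category labels.
#' @export
categoryCentroids <- function(embeddings, labels = NULL) {
  if (is(embeddings, "SummarizedExperiment")) {
    X <- embeddingMatrix(embeddings)
    labels <- embeddingCategories(embeddings)
  } else X <- as.matrix(embeddings)
  if (is.null(labels)) stop("category labels required")
  lev <- sort(unique(labels))
  cent <- t(matrix(vapply(lev, function(l)
    colMeans(X[labels == l, , drop = FALSE]), numeric(ncol(X))),
    nrow = ncol(X)))
  rownames(cent) <- if (is.numeric(lev) &&
                        all(lev %in% (seq_along(MATERIAL_CATEGORIES) - 1L)))
    MATERIAL_CATEGORIES[lev + 1L] else as.character(lev)
  cent
}

#' Euclidean distance matrix between category centroids
#'
#' @param centroids matrix from [categoryCentroids()].
#' @return A [DistanceMatrix-class] (latent flavour: symmetric,
#'   non-negative, zero diagonal).
#' @export
centroidDistanceMatrix <- function(centroids) {
  d <- as.matrix(dist(centroids))
  new("DistanceMatrix", values = d, flavor = "latent")
}

#' Pearson correlation between two distance matrices
#'
#' Correlates the upper triangles (21 unique pairs for 7 categories) of two
#' category-level distance matrices with matching labels.
#'
#' @param a,b [DistanceMatrix-class] objects over the same categories in
#'   the same order.
#' @return Pearson r.
#' @export
matrixCorrelation <- function(a, b) {
  va <- distanceValues(a); vb <- distanceValues(b)
  if (!identical(dim(va), dim(vb)))
    stop("distance matrices differ in size")
  if (!identical(rownames(va), rownames(vb)))
    stop("category labels do not match")
  cor(upperTri(va), upperTri(vb))
}

# ---- exact t-SNE (no approximation; intended for <= a few hundred points) --

# perplexity-calibrated conditional affinities
.tsneAffinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-Di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sp) + beta * sum(Di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else { betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

.tsne <- function(X, perplexity = 10, maxIter = 600, eta = 100, seed = 1L) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  P <- .tsneAffinities(D2, perplexity)
  withSeed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
    Pex <- P * 12  # early exaggeration
    for (iter in seq_len(maxIter)) {
      Puse <- if (iter <= 100) Pex else P
      num <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), .Machine$double.eps)
      W <- (Puse - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      mom <- if (iter < 250) 0.5 else 0.8
      gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8),
                    0.01)
      dY <- mom * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' 2-D t-SNE view of the material embeddings
#'
#' Visualization aid only: embeds the per-material points into two
#' dimensions with an exact t-SNE (fine for dozens of points). The layout
#' is deterministic given `seed`. Use [tsneFidelity()] to check how
#' faithfully the 2-D map preserves category-centroid distances.
#'
#' @param embeddings `SummarizedExperiment` from [materialEmbeddings()].
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity; must be below the number of
#'   materials (default 10, suited to ~81 points).
#' @param maxIter gradient-descent iterations.
#' @return Matrix (materials x 2) with material ids as rownames and the
#'   category ids as the `categories` attribute.
#' @export
tsneEmbed <- function(embeddings, seed = 1L, perplexity = 10,
                      maxIter = 600) {
  X <- embeddingMatrix(embeddings)
  if (perplexity >= nrow(X))
    stop("perplexity must be smaller than the number of materials")
  Y <- .tsne(X, perplexity = perplexity, maxIter = maxIter, seed = seed)
  rownames(Y) <- SummarizedExperiment::colData(embeddings)$material_id
  attr(Y, "categories") <- embeddingCategories(embeddings)
  Y
}

#' Fidelity of the 2-D t-SNE map
#'
#' Correlates category-centroid distances in the 2-D t-SNE map with those
#' in the k-D latent PCs space.
#'
#' @param tsneCoords output of [tsneEmbed()].
#' @param embeddings the embeddings that were mapped.
#' @return Pearson r over the category pairs.
#' @export
tsneFidelity <- function(tsneCoords, embeddings) {
  labels <- embeddingCategories(embeddings)
  c2 <- categoryCentroids(tsneCoords, labels)
  ck <- categoryCentroids(embeddings)
  matrixCorrelation(centroidDistanceMatrix(c2), centroidDistanceMatrix(ck))
}
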