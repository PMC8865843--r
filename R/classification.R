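# Leave-one-material-per-category-out linear classification with a
# label-shuffling bootstrap null.

# drop zero-variance feature columns and standardize the rest; linear
# discriminants are affine-invariant, and MASS::lda's constant-variable
# guard uses an absolute tolerance that tiny-scale PC columns would trip
prepFeatures <- function(X) {
  sds <- apply(X, 2, sd)
  keep <- which(sds > 0)
  if (!length(keep)) stop("all embedding columns are constant")
  scale(X[, keep, drop = FALSE])
}

# deterministic fold scheme: fold count = largest category size; in fold i
# each category contributes its ((i - 1) mod size)-th material (materials
# sorted by id within category)
looFolds <- function(materialIds, labels) {
  lev <- sort(unique(labels))
  sizes <- vapply(lev, function(l) sum(labels == l), 0L)
  if (any(sizes < 2))
    stop("every category needs at least two materials for LOO folds")
  nFold <- max(sizes)
  byCat <- lapply(lev, function(l) sort(which(labels == l)))
  lapply(seq_len(nFold), function(i)
    vapply(seq_along(lev), function(c)
      byCat[[c]][(i - 1L) %% sizes[c] + 1L], 0L))
}

#' Leave-one-material-per-category-out linear classification
#'
#' Classifies per-material embeddings in the latent PCs space with a linear
#' discriminant, iteratively leaving out one material per category: the
#' number of folds equals the largest category size, and within each
#' category materials (sorted by id) are cycled through the folds. Accuracy
#' is the fraction of correct held-out predictions over all folds, in
#' percent.
#'
#' @param embeddings `SummarizedExperiment` from [materialEmbeddings()] or a
#'   matrix (materials x k).
#' @param labels category labels per material; defaults to the embeddings'
#'   ground-truth `category_id`. Pass perceptual labels (see
#'   [assignPerceptualLabels()]) to score against perceived categories.
#' @param labelSource tag recorded in the result (`"ground_truth"`,
#'   `"perceptual"`, `"custom"`).
#' @return A [ClassificationResult-class] (null fields NA; see
#'   [bootstrapNull()]).
#' @export
looClassify <- function(embeddings, labels = NULL,
                        labelSource = if (is.null(labels)) "ground_truth"
                                      else "custom") {
  force(labelSource)  # resolve before `labels` is filled in below
  if (is(embeddings, "SummarizedExperiment")) {
    X <- embeddingMatrix(embeddings)
    ids <- SummarizedExperiment::colData(embeddings)$material_id
    if (is.null(labels)) labels <- embeddingCategories(embeddings)
  } else {
    X <- as.matrix(embeddings)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("m%03d", seq_len(nrow(X)))
    if (is.null(labels)) stop("labels required for matrix input")
  }
  labels <- as.integer(labels)
  X <- prepFeatures(X)
  folds <- looFolds(ids, labels)
  preds <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    test <- folds[[i]]
    train <- setdiff(seq_len(nrow(X)), test)
    fit <- suppressWarnings(
      MASS::lda(X[train, , drop = FALSE], grouping = labels[train],
                tol = 1e-8))
    p <- stats::predict(fit, X[test, , drop = FALSE])$class
    preds[[i]] <- data.frame(
      fold = i, material_id = ids[test], true = labels[test],
      predicted = as.integer(as.character(p)), stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, preds)
  acc <- 100 * mean(preds$true == preds$predicted)
  new("ClassificationResult", accuracy = acc, predictions = preds,
      labelSource = labelSource, nullMean = NA_real_,
      nullCI = c(NA_real_, NA_real_), nShuffles = 0L)
}

#' Bootstrap null distribution via label shuffling
#'
#' Repeats the leave-one-material-per-category-out classification
#' `nShuffles` times with category labels randomly permuted over materials,
#' giving the accuracy distribution under the null hypothesis of no
#' relation between embeddings and categories. Returns the mean (the
#' empirical chance level) and the 2.5th/97.5th percentile confidence
#' interval.
#'
#' @inheritParams looClassify
#' @param nShuffles number of label permutations (default 5000; >= 100).
#' @param seed integer seed; output is reproducible given the seed.
#' @return `list(mean =, ci =, accuracies =)` with accuracies in percent.
#' @export
bootstrapNull <- function(embeddings, labels = NULL, nShuffles = 5000L,
                          seed = 1L) {
  if (nShuffles < 100L) stop("'nShuffles' must be at least 100")
  if (is(embeddings, "SummarizedExperiment")) {
    if (is.null(labels)) labels <- embeddingCategories(embeddings)
    X <- embeddingMatrix(embeddings)
    rownames(X) <- SummarizedExperiment::colData(embeddings)$material_id
  } else X <- as.matrix(embeddings)
  labels <- as.integer(labels)
  accs <- withSeed(seed, vapply(seq_len(nShuffles), function(i)
    accuracy(looClassify(X, sample(labels), labelSource = "custom")),
    0))
  list(mean = mean(accs),
       ci = unname(quantile(accs, c(0.025, 0.975))),
       accuracies = accs)
}

#' Classification with bootstrap null in one call
#'
#' Runs [looClassify()] and [bootstrapNull()] and combines them.
#'
#' @inheritParams bootstrapNull
#' @inheritParams looClassify
#' @return A [ClassificationResult-class] with null fields filled.
#' @export
classifyLatentSpace <- function(embeddings, labels = NULL,
                                labelSource = if (is.null(labels))
                                  "ground_truth" else "custom",
                                nShuffles = 5000L, seed = 1L) {
  force(labelSource)
  res <- looClassify(embeddings, labels, labelSource)
  null <- bootstrapNull(embeddings, labels, nShuffles, seed)
  initialize(res, nullMean = null$mean, nullCI = null$ci,
             nShuffles = as.integer(nShuffles))
}
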