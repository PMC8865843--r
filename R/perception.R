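# Rating analyses: z-transform, rating PCA, perceptual distance matrix,
# perceptual label assignment and between-participant agreement.

#' Z-transform descriptor ratings
#'
#' Standardizes the descriptor ratings separately for each participant and
#' each descriptor (population SD), bringing all participants onto a common
#' scale and removing subjective criterion differences.
#'
#' @param raw a [RatingTable-class].
#' @return The z-transformed [RatingTable-class].
#' @export
zTransform <- function(raw) {
  d <- raw@descriptors
  for (p in unique(d$participant_id)) {
    for (dsc in unique(d$descriptor)) {
      i <- d$participant_id == p & d$descriptor == dsc
      v <- d$value[i]
      s <- sqrt(mean((v - mean(v))^2))
      if (s == 0)
        stop(sprintf(
          "zero-variance rating slice: participant %s, descriptor %s",
          p, dsc))
      d$value[i] <- (v - mean(v)) / s
    }
  }
  initialize(raw, descriptors = d, zTransformed = TRUE)
}

# materials x 7 matrix of participant-averaged descriptor z-scores
pooledDescriptorMatrix <- function(table) {
  d <- table@descriptors
  agg <- aggregate(value ~ material_id + descriptor, d, mean)
  ids <- sort(unique(agg$material_id))
  m <- matrix(NA_real_, length(ids), length(HAPTIC_DESCRIPTORS),
              dimnames = list(ids, HAPTIC_DESCRIPTORS))
  m[cbind(match(agg$material_id, ids),
          match(agg$descriptor, HAPTIC_DESCRIPTORS))] <- agg$value
  m
}

#' PCA of the pooled ratings
#'
#' Decomposes the materials x 7 matrix of descriptor z-scores averaged
#' across participants; the first components summarize the perceptual
#' representation because ratings on different descriptors are correlated.
#'
#' @param table a z-transformed [RatingTable-class].
#' @return A [LatentPCSpace-class] over the descriptor space (all 7
#'   components retained; explained-variance ratios sum to 1).
#' @export
ratingsPCA <- function(table) {
  if (!table@zTransformed)
    stop("z-transform the ratings first (zTransform())")
  m <- pooledDescriptorMatrix(table)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  new("LatentPCSpace",
      rotation = pc$rotation, center = pc$center, evr = evr,
      k = as.integer(ncol(m)), threshold = 1,
      projected = pc$x,
      segmentInfo = S4Vectors::DataFrame(material_id = rownames(m)))
}

#' Perceptual distance matrix from ratings
#'
#' Each material is summarized by its participant-averaged descriptor
#' z-score vector. For every pair of materials the vectors are correlated;
#' the correlations are averaged per category pair (distinct-material pairs
#' on the diagonal), giving a category-level correlation `rho` that is
#' mapped to a distance `delta = 2 * (1 - rho)`. The square-root variant
#' `sqrt(2 * (1 - rho))` (the conventional correlation distance) is
#' available via `method = "sqrt"`.
#'
#' @param table a z-transformed [RatingTable-class].
#' @param method `"as-printed"` (default) for `2 * (1 - rho)` or `"sqrt"`.
#' @return A [DistanceMatrix-class] (perceptual flavour).
#' @export
perceptualDistanceMatrix <- function(table,
                                     method = c("as-printed", "sqrt")) {
  method <- match.arg(method)
  if (!table@zTransformed)
    stop("z-transform the ratings first (zTransform())")
  m <- pooledDescriptorMatrix(table)
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("%d material(s) with constant rating vector excluded",
                    sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
  }
  cats <- table@materials$category_id[
    match(rownames(m), table@materials$material_id)]
  rho <- cor(t(m))
  lev <- sort(unique(cats))
  nCat <- length(lev)
  out <- matrix(NA_real_, nCat, nCat)
  for (i in seq_len(nCat)) {
    for (j in i:nCat) {
      a <- which(cats == lev[i]); b <- which(cats == lev[j])
      block <- rho[a, b, drop = FALSE]
      if (i == j) {
        vals <- block[upper.tri(block)]  # distinct pairs only
      } else vals <- as.vector(block)
      out[i, j] <- out[j, i] <- mean(vals)
    }
  }
  delta <- 2 * (1 - out)
  if (method == "sqrt") delta <- sqrt(delta)
  nm <- if (all(lev %in% (seq_along(MATERIAL_CATEGORIES) - 1L)))
    MATERIAL_CATEGORIES[lev + 1L] else as.character(lev)
  dimnames(delta) <- list(nm, nm)
  new("DistanceMatrix", values = delta, flavor = "perceptual")
}

# per-participant argmax over the seven similarity scales; ties break to
# the lowest category index (with a message)
participantLabels <- function(table) {
  ct <- table@categories
  catLevels <- MATERIAL_CATEGORIES[seq_along(unique(ct$category))]
  out <- list()
  ties <- 0L
  for (p in unique(ct$participant_id)) {
    sub <- ct[ct$participant_id == p, ]
    wide <- matrix(NA_real_, length(unique(sub$material_id)),
                   length(catLevels))
    ids <- sort(unique(sub$material_id))
    wide[cbind(match(sub$material_id, ids),
               match(sub$category, catLevels))] <- sub$similarity
    top <- apply(wide, 1, function(v) {
      w <- which(v == max(v))
      if (length(w) > 1) ties <<- ties + 1L
      w[1]
    })
    out[[as.character(p)]] <- data.frame(
      participant_id = p, material_id = ids,
      label = top - 1L, stringsAsFactors = FALSE)
  }
  if (ties) message(ties, " argmax tie(s) broken to the lowest category index")
  do.call(rbind, out)
}

majorityVote <- function(labels) {
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  as.integer(min(as.integer(winners)))  # ties: lowest category index
}

#' Assign perceptual category labels by majority vote
#'
#' For every participant the highest-rated category of each material is
#' taken; across participants the most frequent label wins (ties break to
#' the lowest category index).
#'
#' @param table a [RatingTable-class].
#' @return data.frame with columns `material_id`, `ground_truth`,
#'   `perceptual_label`, `vote_count`.
#' @export
assignPerceptualLabels <- function(table) {
  pl <- participantLabels(table)
  ids <- sort(unique(pl$material_id))
  lab <- vapply(ids, function(m) majorityVote(pl$label[pl$material_id == m]),
                0L)
  votes <- vapply(ids, function(m) {
    l <- pl$label[pl$material_id == m]
    as.integer(sum(l == majorityVote(l)))
  }, 0L)
  data.frame(
    material_id = ids,
    ground_truth = table@materials$category_id[
      match(ids, table@materials$material_id)],
    perceptual_label = lab,
    vote_count = votes, stringsAsFactors = FALSE)
}

#' Between-participant agreement level
#'
#' Leave-one-participant-out: each participant's per-material labels are
#' predicted by the majority vote of the remaining participants; accuracy is
#' averaged over participants and materials.
#'
#' @param table a [RatingTable-class].
#' @return Agreement in percent.
#' @export
agreementLevel <- function(table) {
  pl <- participantLabels(table)
  parts <- unique(pl$participant_id)
  if (length(parts) < 2) stop("at least two participants required")
  correct <- 0L; total <- 0L
  for (p in parts) {
    held <- pl[pl$participant_id == p, ]
    rest <- pl[pl$participant_id != p, ]
    for (i in seq_len(nrow(held))) {
      pred <- majorityVote(rest$label[rest$material_id == held$material_id[i]])
      correct <- correct + (pred == held$label[i])
      total <- total + 1L
    }
  }
  100 * correct / total
}
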