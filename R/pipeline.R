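# End-to-end orchestration: simulate -> preprocess -> train -> analyze ->
# classify -> probe (-> sweep), with stage-level caching keyed on content
# hashes of the config subsections, a run log, and a consolidated report.

#' Assemble and validate a pipeline configuration
#'
#' All downstream stages read their parameters exclusively from this
#' object; a serialized copy is written next to the outputs. Defaults are
#' the canonical study conditions (11 participants, 81 materials in 7
#' categories, 10 s at 3200 Hz, 16-feature bottleneck trained 50 epochs).
#'
#' @param outdir output directory for all artifacts.
#' @param seed master seed; every stage derives its randomness from it.
#' @param generator,preprocessing,model,analysis named lists overriding
#'   individual defaults (see the vignette for the full parameter table).
#' @return A validated `PipelineConfig` (a classed list).
#' @export
makePipelineConfig <- function(outdir, seed = 1L, generator = list(),
                               preprocessing = list(), model = list(),
                               analysis = list()) {
  merge <- function(def, user) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    generator = merge(list(
      nCategories = 7L,
      materialsPerCategory = c(12L, 12L, 12L, 12L, 11L, 11L, 11L),
      nParticipants = 11L, durationS = 10, rateHz = 3200,
      ratingNoiseSD = 0.8, confusion = 0.45, confusionMode = "spectral",
      driftGain = 0.6, noiseGain = 0.1, floorGain = 0.35), generator),
    preprocessing = merge(list(
      lowHz = 10, highHz = 800, windowMs = 80, trainFraction = 0.95),
      preprocessing),
    model = merge(list(
      latentDims = 16L, epochs = 50L, batchSize = 128L, lr = 1e-3), model),
    analysis = merge(list(
      varianceThreshold = 0.95, nShuffles = 5000L, tsnePerplexity = 10,
      probeN = 830L, probeAmplitude = 0.25, probePhases = 8L), analysis))
  winLen <- cfg$preprocessing$windowMs * cfg$generator$rateHz / 1000
  nWin <- cfg$generator$durationS * cfg$generator$rateHz / winLen
  if (abs(nWin - round(nWin)) > 1e-9)
    stop("durationS must be a whole number of windows")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [readPipelineConfig()] returns a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  makePipelineConfig(outdir = y$outdir, seed = y$seed,
                     generator = y$generator %||% list(),
                     preprocessing = y$preprocessing %||% list(),
                     model = y$model %||% list(),
                     analysis = y$analysis %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readPipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# content hash of an R object (used as the stage cache key)
contentHash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

stageLog <- function(cfg, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  cat(line, "\n", file = file.path(cfg$outdir, "pipeline.log"),
      append = TRUE)
}

# run `fn` unless the stage's cache key is unchanged and artifacts exist
withStageCache <- function(cfg, stage, key, artifacts, fn) {
  dir <- file.path(cfg$outdir, stage)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keyFile <- file.path(dir, ".key")
  hash <- contentHash(key)
  paths <- file.path(dir, artifacts)
  if (file.exists(keyFile) && identical(readLines(keyFile, warn = FALSE),
                                        hash) && all(file.exists(paths))) {
    stageLog(cfg, stage, "cache hit, skipping")
    return(invisible(dir))
  }
  stageLog(cfg, stage, "running")
  fn(dir)
  writeLines(hash, keyFile)
  invisible(dir)
}

stagePath <- function(cfg, stage, file) file.path(cfg$outdir, stage, file)

pipelineSimulate <- function(cfg) {
  g <- cfg$generator
  withStageCache(cfg, "simulate", list(g, cfg$seed),
                 c("manifest.csv", "library.rds", "ratings_descriptors.csv"),
                 function(dir) {
    lib <- makeMaterialLibrary(g$nCategories, g$materialsPerCategory,
                               seed = cfg$seed)
    parts <- makeParticipants(g$nParticipants, seed = childSeed(cfg$seed, 1),
                              ratingNoiseSD = g$ratingNoiseSD)
    writeRecordingSet(lib, parts, dir, durationS = g$durationS,
                      rateHz = g$rateHz, seed = childSeed(cfg$seed, 2),
                      driftGain = g$driftGain, noiseGain = g$noiseGain,
                      floorGain = g$floorGain)
    ratings <- synthRatings(lib, parts, seed = childSeed(cfg$seed, 3),
                            confusion = g$confusion,
                            confusionMode = g$confusionMode)
    writeRatings(ratings, dir)
    saveRDS(lib, file.path(dir, "library.rds"))
    saveRDS(parts, file.path(dir, "participants.rds"))
  })
}

pipelinePreprocess <- function(cfg) {
  p <- cfg$preprocessing
  withStageCache(cfg, "preprocess",
                 list(cfg$generator, p, cfg$seed),
                 c("train.rds", "test.rds", "full.rds"),
                 function(dir) {
    simDir <- file.path(cfg$outdir, "simulate")
    manifest <- read.csv(file.path(simDir, "manifest.csv"),
                         stringsAsFactors = FALSE)
    sets <- lapply(seq_len(nrow(manifest)), function(i) {
      rec <- readRecording(simDir, manifest[i, ])
      segmentRecording(bandpassFilter(rec, p$lowHz, p$highHz), p$windowMs)
    })
    all <- combineSegmentSets(sets)
    sp <- splitSegments(all, p$trainFraction, seed = childSeed(cfg$seed, 4))
    train <- normalizeSegments(sp$train)
    k <- normalizationConstants(train)
    test <- normalizeSegments(sp$test, k)
    full <- normalizeSegments(all, k)
    saveRDS(train, file.path(dir, "train.rds"))
    saveRDS(test, file.path(dir, "test.rds"))
    saveRDS(full, file.path(dir, "full.rds"))
    stageLog(cfg, "preprocess",
             sprintf("%d segments (%d train / %d test)", nSegments(all),
                     nSegments(train), nSegments(test)))
  })
}

pipelineTrain <- function(cfg, latentDim) {
  m <- cfg$model
  stage <- sprintf("train_d%03d", latentDim)
  withStageCache(cfg, stage,
                 list(cfg$generator, cfg$preprocessing, m, latentDim,
                      cfg$seed),
                 c("model.rds", "loss.csv"),
                 function(dir) {
    train <- readRDS(stagePath(cfg, "preprocess", "train.rds"))
    test <- readRDS(stagePath(cfg, "preprocess", "test.rds"))
    spec <- buildAutoencoder(latentDim)
    model <- trainAutoencoder(spec, train, test, epochs = m$epochs,
                              batchSize = m$batchSize, lr = m$lr,
                              seed = childSeed(cfg$seed, 5 + latentDim))
    saveRDS(model, file.path(dir, "model.rds"))
    write.csv(trainingReport(model), file.path(dir, "loss.csv"),
              row.names = FALSE)
  })
}

pipelineAnalyze <- function(cfg, latentDim) {
  a <- cfg$analysis
  stage <- sprintf("analyze_d%03d", latentDim)
  withStageCache(cfg, stage,
                 list(cfg$generator, cfg$preprocessing, cfg$model, a,
                      latentDim, cfg$seed),
                 c("summary.rds", "latent_distances.csv",
                   "perceptual_distances.csv", "labels.csv"),
                 function(dir) {
    model <- readRDS(stagePath(cfg, sprintf("train_d%03d", latentDim),
                               "model.rds"))
    train <- readRDS(stagePath(cfg, "preprocess", "train.rds"))
    test <- readRDS(stagePath(cfg, "preprocess", "test.rds"))
    full <- readRDS(stagePath(cfg, "preprocess", "full.rds"))
    codes <- encodeSegments(model, full)
    pcs <- fitLatentPCA(codes, a$varianceThreshold)
    emb <- materialEmbeddings(pcs)
    cent <- categoryCentroids(emb)
    latDist <- centroidDistanceMatrix(cent)
    ratings <- zTransform(readRatings(file.path(cfg$outdir, "simulate")))
    percDist <- perceptualDistanceMatrix(ratings)
    labels <- assignPerceptualLabels(ratings)
    rpca <- ratingsPCA(ratings)
    tsne <- tsneEmbed(emb, seed = childSeed(cfg$seed, 6),
                      perplexity = min(a$tsnePerplexity,
                                       ncol(emb) %/% 3))
    summary <- list(
      latentDim = latentDim,
      compressionRate = compressionRate(latentDim),
      trainR2 = reconstructionR2(model, train),
      testR2 = reconstructionR2(model, test),
      kAt95 = retainedDim(pcs),
      evr = explainedVariance(pcs),
      ratingsPC12 = 100 * sum(explainedVariance(rpca)[1:2]),
      latentPerceptualR = matrixCorrelation(latDist, percDist),
      tsneFidelity = tsneFidelity(tsne, emb),
      agreement = agreementLevel(ratings))
    saveRDS(list(summary = summary, pcs = pcs, emb = emb,
                 latDist = latDist, percDist = percDist, labels = labels),
            file.path(dir, "summary.rds"))
    write.csv(distanceValues(latDist), file.path(dir, "latent_distances.csv"))
    write.csv(distanceValues(percDist),
              file.path(dir, "perceptual_distances.csv"))
    write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    write.csv(data.frame(material_id = rownames(tsne), x = tsne[, 1],
                         y = tsne[, 2]),
              file.path(dir, "tsne.csv"), row.names = FALSE)
  })
}

pipelineClassify <- function(cfg, latentDim) {
  a <- cfg$analysis
  stage <- sprintf("classify_d%03d", latentDim)
  withStageCache(cfg, stage,
                 list(cfg$generator, cfg$preprocessing, cfg$model, a,
                      latentDim, cfg$seed),
                 "classification.json",
                 function(dir) {
    art <- readRDS(stagePath(cfg, sprintf("analyze_d%03d", latentDim),
                             "summary.rds"))
    emb <- art$emb
    gt <- looClassify(emb)
    percLabels <- art$labels$perceptual_label[
      match(SummarizedExperiment::colData(emb)$material_id,
            art$labels$material_id)]
    # materials whose perceived category has a single member cannot take
    # part in leave-one-material-per-category folds
    sizes <- table(percLabels)
    keep <- percLabels %in% as.integer(names(sizes[sizes >= 2]))
    if (any(!keep))
      stageLog(cfg, stage, sprintf(
        "%d material(s) in singleton perceived categories dropped from the perceptual-label classification",
        sum(!keep)))
    pc <- looClassify(emb[, keep], percLabels[keep],
                      labelSource = "perceptual")
    null <- bootstrapNull(emb, nShuffles = a$nShuffles,
                          seed = childSeed(cfg$seed, 7))
    out <- list(latentDim = latentDim,
                accuracy_ground_truth = accuracy(gt),
                accuracy_perceptual = accuracy(pc),
                null_mean = null$mean, null_ci = null$ci,
                n_shuffles = a$nShuffles)
    jsonlite::write_json(out, file.path(dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(rbind(gt@predictions, pc@predictions),
              file.path(dir, "predictions.csv"), row.names = FALSE)
  })
}

pipelineProbe <- function(cfg, latentDim) {
  a <- cfg$analysis
  stage <- sprintf("probe_d%03d", latentDim)
  withStageCache(cfg, stage,
                 list(cfg$generator, cfg$preprocessing, cfg$model, a,
                      latentDim, cfg$seed),
                 c("tuning_curves.csv", "tuning_summary.csv"),
                 function(dir) {
    model <- readRDS(stagePath(cfg, sprintf("train_d%03d", latentDim),
                               "model.rds"))
    art <- readRDS(stagePath(cfg, sprintf("analyze_d%03d", latentDim),
                             "summary.rds"))
    bank <- makeSinusoidBank(n = a$probeN, amplitude = a$probeAmplitude,
                             nPhases = a$probePhases,
                             rateHz = cfg$generator$rateHz)
    curves <- probeTuning(model, art$pcs, bank)
    curves <- clusterTuning(curves, seed = childSeed(cfg$seed, 8))
    cmp <- compareToAfferents(curves)
    long <- data.frame(
      dimension = rep(rownames(curves@sensitivity),
                      each = length(curves@frequencies)),
      frequency = rep(curves@frequencies,
                      times = nrow(curves@sensitivity)),
      sensitivity = as.vector(t(curves@sensitivity)))
    write.csv(long, file.path(dir, "tuning_curves.csv"), row.names = FALSE)
    write.csv(data.frame(dimension = rownames(curves@sensitivity),
                         tuning_Hz = curves@summaryHz,
                         cluster = as.character(curves@cluster)),
              file.path(dir, "tuning_summary.csv"), row.names = FALSE)
    saveRDS(list(curves = curves, comparison = cmp),
            file.path(dir, "tuning.rds"))
  })
}

pipelineReport <- function(cfg) {
  dims <- cfg$model$latentDims
  sections <- lapply(dims, function(d) {
    s <- readRDS(stagePath(cfg, sprintf("analyze_d%03d", d),
                           "summary.rds"))$summary
    cls <- jsonlite::read_json(stagePath(cfg, sprintf("classify_d%03d", d),
                                         "classification.json"),
                               simplifyVector = TRUE)
    tun <- readRDS(stagePath(cfg, sprintf("probe_d%03d", d), "tuning.rds"))
    list(latentDim = d, compressionRate = s$compressionRate,
         trainR2 = s$trainR2, testR2 = s$testR2, kAt95 = s$kAt95,
         latentPerceptualR = s$latentPerceptualR,
         ratingsPC12 = s$ratingsPC12, agreement = s$agreement,
         tsneFidelity = s$tsneFidelity,
         accuracy_ground_truth = cls$accuracy_ground_truth,
         accuracy_perceptual = cls$accuracy_perceptual,
         null_mean = cls$null_mean, null_ci = cls$null_ci,
         tuningClusters = as.list(table(tun$curves@cluster)),
         afferentMatch = tun$comparison$pass)
  })
  report <- list(seed = cfg$seed, models = sections,
                 sweep = if (length(dims) > 1) "see sweep.csv" else "skipped")
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- file.path(cfg$outdir, "report.txt")
  lines <- c("haptic efficient-coding pipeline report", "")
  for (s in sections) {
    lines <- c(lines, sprintf(
      "latentDim %d (%.2f%% compression): R2 train %.3f / test %.3f; k@%.0f%% = %d; acc GT %.1f%% / perceptual %.1f%% (null %.1f%% [%.1f, %.1f]); latent-perceptual r = %.3f; agreement %.1f%%",
      s$latentDim, s$compressionRate, s$trainR2, s$testR2,
      100 * cfg$analysis$varianceThreshold, s$kAt95,
      s$accuracy_ground_truth, s$accuracy_perceptual, s$null_mean,
      s$null_ci[1], s$null_ci[2], s$latentPerceptualR, s$agreement))
  }
  writeLines(lines, txt)
  report
}

#' Run the full analysis pipeline
#'
#' Sequences simulate -> preprocess -> train -> analyze -> classify ->
#' probe for every configured bottleneck size and writes a consolidated
#' report (`report.json`, `report.txt`) plus per-stage artifacts under the
#' configured output directory. Stages are cached on content hashes of
#' their config subsections: re-running with an unchanged config reuses
#' every artifact and reproduces the report byte-identically.
#'
#' @param config a `PipelineConfig` from [makePipelineConfig()].
#' @return The report, invisibly (a nested list).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  writePipelineConfig(config, file.path(config$outdir, "config.yaml"))
  pipelineSimulate(config)
  pipelinePreprocess(config)
  for (d in config$model$latentDims) {
    pipelineTrain(config, d)
    pipelineAnalyze(config, d)
    pipelineClassify(config, d)
    pipelineProbe(config, d)
  }
  invisible(pipelineReport(config))
}

#' Compression sweep
#'
#' Re-runs training and the latent analyses over a list of bottleneck
#' sizes and tabulates, per size: compression rate, train/validation
#' reconstruction R2, classification accuracy with perceptual labels, and
#' the latent-perceptual distance-matrix correlation.
#'
#' @param config a `PipelineConfig`.
#' @param latentDims integer vector of bottleneck sizes (non-empty); the
#'   default set spans 6.25\% to 100\% compression rate.
#' @return data.frame, one row per bottleneck size (also written to
#'   `sweep.csv` in the output directory).
#' @export
compressionSweep <- function(config,
                             latentDims = c(16L, 64L, 128L, 192L, 256L)) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!length(latentDims)) stop("empty latentDims list")
  config$model$latentDims <- latentDims
  runPipeline(config)
  rows <- lapply(latentDims, function(d) {
    s <- readRDS(stagePath(config, sprintf("analyze_d%03d", d),
                           "summary.rds"))$summary
    cls <- jsonlite::read_json(
      stagePath(config, sprintf("classify_d%03d", d), "classification.json"),
      simplifyVector = TRUE)
    data.frame(latentDim = d, compressionRate = s$compressionRate,
               trainR2 = s$trainR2, valR2 = s$testR2,
               accuracyPerceptual = cls$accuracy_perceptual,
               latentPerceptualR = s$latentPerceptualR)
  })
  out <- do.call(rbind, rows)
  write.csv(out, file.path(config$outdir, "sweep.csv"), row.names = FALSE)
  out
}
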