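# End-to-end orchestration: simulate -> train -> latents -> encode -> roi ->
# prefmap -> decode -> stats -> report. Every stage reads its inputs from the
# previous stage's artifacts on disk, writes TSV/JSON artifacts plus a
# manifest (parameters, seed, input/output checksums), and derives its RNG
# seed from the global seed, so stages can be re-run independently and the
# whole pipeline is deterministic under a fixed configuration.

.pipelineStages <- c("simulate", "train", "latents", "encode", "roi",
                     "prefmap", "decode", "stats", "report")

#' Build a pipeline configuration
#'
#' Presets fix the problem sizes: `ci` is a minutes-scale smoke
#' configuration, `desk` the default analysis scale, and `paper` the
#' full-scale protocol (about 8000 training faces and the complete
#' 480-model hyperparameter grid; expect long runtimes).
#'
#' @param preset One of `"ci"`, `"desk"`, `"paper"`.
#' @param seed Global integer seed; every stage derives its own substream.
#' @param outDir Output directory for stage artifacts.
#' @param ... Named overrides of individual preset fields.
#' @return A named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(preset = c("desk", "ci", "paper"), seed = 1L,
                           outDir = tempfile("latentfaces_"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ci = list(nTrain = 120L, side = 32L, nVoxels = 60L, repeats = 10L,
              snr = 1.5, singleDimFraction = 0.3, epochs = 8L,
              hidden = c(64L, 32L), latentDim = 6L, gammas = c(0, 10),
              gridSeeds = 1L, batchSize = 24L, resamples = 200L,
              reliabilitySplits = 20L),
    desk = list(nTrain = 500L, side = 32L, nVoxels = 200L, repeats = 50L,
                snr = 1.5, singleDimFraction = 0.3, epochs = 15L,
                hidden = c(128L, 64L), latentDim = 8L, gammas = c(0, 10, 30),
                gridSeeds = 1:2, batchSize = 32L, resamples = 1000L,
                reliabilitySplits = 100L),
    paper = list(nTrain = 8000L, side = 64L, nVoxels = 2000L, repeats = 50L,
                 snr = 1.5, singleDimFraction = 0.3, epochs = 50L,
                 hidden = c(256L, 128L), latentDim = 24L,
                 gammas = c(0, 10, 20, 30, 40, 50, 100), gridSeeds = 1:10,
                 batchSize = 64L, resamples = 1000L,
                 reliabilitySplits = 100L))
  dots <- list(...)
  base[names(dots)] <- dots
  structure(c(list(preset = preset, seed = as.integer(seed), outDir = outDir),
              base),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set `preset`, `seed`, `outDir` and any preset field override
#' (nTrain, side, nVoxels, ...); unset fields fall back to the preset's
#' values.
#'
#' @param path Path to a YAML file.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- if (is.null(y$preset)) "desk" else y$preset
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  outDir <- if (is.null(y$outDir)) tempfile("latentfaces_") else y$outDir
  overrides <- y[setdiff(names(y), c("preset", "seed", "outDir"))]
  do.call(pipelineConfig,
          c(list(preset = preset, seed = seed, outDir = outDir), overrides))
}

.stageDir <- function(config, stage) file.path(config$outDir, stage)

.artifact <- function(config, stage, file) file.path(.stageDir(config, stage), file)

.requireArtifact <- function(config, stage, file) {
  p <- .artifact(config, stage, file)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s': run stage '%s' first", file, stage),
         call. = FALSE)
  }
  p
}

.writeManifest <- function(config, stage, inputs, outputs, params) {
  md5 <- function(paths) {
    if (!length(paths)) return(list())
    x <- as.list(tools::md5sum(paths))
    # key by path relative to the output root so manifests are
    # location-independent
    names(x) <- sub(paste0("^", normalizePath(config$outDir, mustWork = FALSE),
                           "/?"), "", normalizePath(paths, mustWork = FALSE))
    x
  }
  manifest <- list(stage = stage, preset = config$preset,
                   seed = deriveSeed(config$seed, match(stage, .pipelineStages)),
                   params = params, inputs = md5(inputs), outputs = md5(outputs))
  jsonlite::write_json(manifest, .artifact(config, stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a single pipeline stage
#'
#' @param name Stage name, one of simulate, train, latents, encode, roi,
#'   prefmap, decode, stats, report.
#' @param config A [pipelineConfig()].
#' @return Invisibly, the stage directory.
#' @export
runStage <- function(name, config) {
  stopifnot(inherits(config, "pipelineConfig"))
  name <- match.arg(name, .pipelineStages)
  dir.create(.stageDir(config, name), recursive = TRUE, showWarnings = FALSE)
  seed <- deriveSeed(config$seed, match(name, .pipelineStages))
  fn <- get(paste0(".stage_", name), mode = "function")
  fn(config, seed)
  invisible(.stageDir(config, name))
}

#' Run the full pipeline
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, the output directory.
#' @export
runPipeline <- function(config) {
  for (s in .pipelineStages) runStage(s, config)
  invisible(config$outDir)
}

.stage_simulate <- function(config, seed) {
  spec <- defaultFactorSpec()
  ds <- sampleFaceDataset(spec, nTrain = config$nTrain, side = config$side,
                          seed = seed, testIrrelevantScale = 1)
  truth <- makeGroundTruth(latentDim = nrow(spec), nVoxels = config$nVoxels,
                           singleDimVoxels = round(config$singleDimFraction *
                                                     config$nVoxels),
                           seed = deriveSeed(seed, 1))
  truth <- setNoiseSd(truth, noiseSdForSnr(truth, trainFactors(ds), config$snr))
  fve <- simulateVoxelResponses(trainFactors(ds), testFactors(ds), truth,
                                repeats = config$repeats,
                                seed = deriveSeed(seed, 2))
  rel <- splitHalfReliability(fve, nSplits = config$reliabilitySplits,
                              seed = deriveSeed(seed, 3))
  parcel <- rep(c("OFA", "FFA", "STS"), length.out = config$nVoxels)
  loc <- simulateLocalizer(rep(TRUE, config$nVoxels), shift = 3,
                           parcelLabels = parcel, seed = deriveSeed(seed, 4))

  out <- character(0)
  wr <- function(m, f) {
    p <- .artifact(config, "simulate", f); writeMatrixTsv(m, p); out <<- c(out, p); p
  }
  wr(trainFactors(ds), "train_factors.tsv")
  wr(testFactors(ds), "test_factors.tsv")
  wr(imagesToMatrix(trainImages(ds)), "train_images.tsv")
  wr(imagesToMatrix(testImages(ds)), "test_images.tsv")
  wr(trainResponses(fve), "train_responses.tsv")
  wr(testResponses(fve), "test_responses.tsv")
  wr(encodingWeights(truth), "truth_W.tsv")
  wr(cbind(bias = faceBias(truth)), "truth_b.tsv")
  wr(cbind(reliability = rel, selectivity = selectivity(loc)), "voxel_scores.tsv")
  p <- .artifact(config, "simulate", "parcels.tsv")
  utils::write.table(data.frame(voxel = seq_along(parcel), parcel = parcel),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(out, p)
  .writeManifest(config, "simulate", character(0), out,
                 config[c("nTrain", "side", "nVoxels", "repeats", "snr")])
}

.writeVaeModel <- function(model, path) {
  obj <- list(params = lapply(model@params, function(m) unclass(m)),
              discriminator = lapply(model@discriminator, function(m) unclass(m)),
              config = modelConfig(model),
              trainingLog = trainingLog(model))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
}

.readVaeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(lst, ref) {
    lapply(lst, function(m) if (is.matrix(m)) m else as.numeric(m))
  }
  cfg <- obj$config
  cfg$hidden <- as.integer(cfg$hidden)
  cfg <- structure(cfg, class = "vaeConfig")
  new("VaeModel", params = fix(obj$params), discriminator = fix(obj$discriminator),
      config = unclass(cfg), trainingLog = as.data.frame(obj$trainingLog))
}

.stage_train <- function(config, seed) {
  imgs <- readMatrixTsv(.requireArtifact(config, "simulate", "train_images.tsv"))
  factors <- readMatrixTsv(.requireArtifact(config, "simulate", "train_factors.tsv"))
  grid <- hyperparameterGrid(latentDims = config$latentDim, betas = 1,
                             gammas = config$gammas, seeds = config$gridSeeds,
                             epochs = config$epochs, side = config$side,
                             hidden = config$hidden, batchSize = config$batchSize)
  results <- lapply(grid, function(cfg) {
    cfg$seed <- deriveSeed(seed, cfg$seed + 100L * cfg$gamma)
    model <- trainVae(imgs, cfg)
    sc <- disentanglementScore(extractLatents(model, imgs), factors)
    list(config = cfg, score = sc$score, model = model)
  })
  best <- which.max(vapply(results, function(r) r$score, numeric(1)))
  scores <- data.frame(
    family = vapply(results, function(r) r$config$family, character(1)),
    gamma = vapply(results, function(r) r$config$gamma, numeric(1)),
    seed = vapply(results, function(r) r$config$seed, integer(1)),
    score = vapply(results, function(r) r$score, numeric(1)))
  out <- character(0)
  p <- .artifact(config, "train", "grid_scores.tsv")
  utils::write.table(scores, p, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(out, p)
  p <- .artifact(config, "train", "model.json")
  .writeVaeModel(results[[best]]$model, p)
  out <- c(out, p)
  .writeManifest(config, "train",
                 .artifact(config, "simulate", "train_images.tsv"), out,
                 config[c("latentDim", "gammas", "epochs")])
}

.stage_latents <- function(config, seed) {
  model <- .readVaeModel(.requireArtifact(config, "train", "model.json"))
  trImgs <- readMatrixTsv(.requireArtifact(config, "simulate", "train_images.tsv"))
  teImgs <- readMatrixTsv(.requireArtifact(config, "simulate", "test_images.tsv"))
  factors <- readMatrixTsv(.artifact(config, "simulate", "train_factors.tsv"))
  trL <- extractLatents(model, trImgs, ids = rownames(trImgs))
  teL <- extractLatents(model, teImgs, ids = rownames(teImgs))
  classes <- classifyDimensions(trL, factors,
                                defaultFactorSpec()$identityRelevant)
  out <- character(0)
  p <- .artifact(config, "latents", "train_latents.tsv"); writeMatrixTsv(trL, p)
  out <- c(out, p)
  p <- .artifact(config, "latents", "test_latents.tsv"); writeMatrixTsv(teL, p)
  out <- c(out, p)
  p <- .artifact(config, "latents", "dimension_classes.json")
  jsonlite::write_json(classes, p, auto_unbox = FALSE)
  out <- c(out, p)
  .writeManifest(config, "latents", .artifact(config, "train", "model.json"),
                 out, list())
}

.stage_encode <- function(config, seed) {
  trL <- readMatrixTsv(.requireArtifact(config, "latents", "train_latents.tsv"))
  teL <- readMatrixTsv(.requireArtifact(config, "latents", "test_latents.tsv"))
  trY <- readMatrixTsv(.requireArtifact(config, "simulate", "train_responses.tsv"))
  teY <- readMatrixTsv(.requireArtifact(config, "simulate", "test_responses.tsv"))
  design <- buildDesign(trL, testIds = rownames(teY))
  fit <- fitEncodingGlm(design, rbind(trY, teY))
  pred <- predictTestResponses(fit, teL)
  rownames(pred) <- rownames(teY)
  res <- evaluateEncoding(pred, teY)
  out <- character(0)
  p <- .artifact(config, "encode", "fit_W.tsv"); writeMatrixTsv(encodingWeights(fit), p)
  out <- c(out, p)
  p <- .artifact(config, "encode", "fit_b.tsv"); writeMatrixTsv(cbind(bias = faceBias(fit)), p)
  out <- c(out, p)
  p <- .artifact(config, "encode", "predicted_test.tsv"); writeMatrixTsv(pred, p)
  out <- c(out, p)
  p <- .artifact(config, "encode", "per_voxel_r.tsv")
  writeMatrixTsv(cbind(r = perVoxelR(res)), p)
  out <- c(out, p)
  .writeManifest(config, "encode",
                 c(.artifact(config, "latents", "train_latents.tsv"),
                   .artifact(config, "simulate", "train_responses.tsv")),
                 out, list())
}

.readParcels <- function(config) {
  df <- utils::read.delim(.requireArtifact(config, "simulate", "parcels.tsv"),
                          stringsAsFactors = FALSE)
  df$parcel
}

.stage_roi <- function(config, seed) {
  scores <- readMatrixTsv(.requireArtifact(config, "simulate", "voxel_scores.tsv"))
  parcel <- .readParcels(config)
  sel <- parcelSelect(scores[, "selectivity"], scores[, "reliability"],
                      parcel = parcel, fraction = 0.1)
  wb <- wholeBrainSelect(selectionMetric(sel))
  df <- data.frame(voxel = seq_along(parcel), parcel = parcel,
                   v_s = sel@vS, v_r = sel@vR, v = selectionMetric(sel),
                   selected = isSelected(sel), whole_brain = wb)
  p <- .artifact(config, "roi", "selection.tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(config, "roi",
                 .artifact(config, "simulate", "voxel_scores.tsv"), p, list())
}

.roiIndexList <- function(config) {
  df <- utils::read.delim(.requireArtifact(config, "roi", "selection.tsv"),
                          stringsAsFactors = FALSE)
  lapply(split(df, df$parcel), function(d) d$voxel[d$selected])
}

.stage_prefmap <- function(config, seed) {
  teY <- readMatrixTsv(.requireArtifact(config, "simulate", "test_responses.tsv"))
  teL <- readMatrixTsv(.requireArtifact(config, "latents", "test_latents.tsv"))
  W <- readMatrixTsv(.requireArtifact(config, "encode", "fit_W.tsv"))
  b <- readMatrixTsv(.requireArtifact(config, "encode", "fit_b.tsv"))
  fit <- new("EncodingFit", W = W, b = as.numeric(b),
             nuisance = matrix(0, 0, ncol(W)), mode = "amplitude")
  rois <- .roiIndexList(config)
  pm <- preferenceProfile(fit, teL, teY, roi = rois)
  out <- character(0)
  p <- .artifact(config, "prefmap", "winner_map.tsv")
  utils::write.table(data.frame(voxel = seq_len(nrow(perDimR(pm))),
                                winner_dim = winners(pm), best_r = pm@bestR),
                     p, sep = "\t", quote = FALSE, row.names = FALSE, na = "none")
  out <- c(out, p)
  p <- .artifact(config, "prefmap", "roi_profiles.tsv")
  writeMatrixTsv(roiProfiles(pm), p, idName = "roi")
  out <- c(out, p)
  p <- .artifact(config, "prefmap", "per_dim_r.tsv")
  writeMatrixTsv(perDimR(pm), p, idName = "voxel")
  out <- c(out, p)
  .writeManifest(config, "prefmap",
                 .artifact(config, "encode", "fit_W.tsv"), out, list())
}

.stage_decode <- function(config, seed) {
  teY <- readMatrixTsv(.requireArtifact(config, "simulate", "test_responses.tsv"))
  teL <- readMatrixTsv(.requireArtifact(config, "latents", "test_latents.tsv"))
  W <- readMatrixTsv(.requireArtifact(config, "encode", "fit_W.tsv"))
  b <- readMatrixTsv(.requireArtifact(config, "encode", "fit_b.tsv"))
  classes <- jsonlite::read_json(
    .requireArtifact(config, "latents", "dimension_classes.json"),
    simplifyVector = TRUE)
  fit <- new("EncodingFit", W = W, b = as.numeric(b),
             nuisance = matrix(0, 0, ncol(W)), mode = "amplitude")
  xHat <- decodeLatents(fit, teY)
  subsets <- list(all = seq_len(nrow(W)))
  for (nm in c("relevant", "irrelevant", "entangled")) {
    if (length(classes[[nm]]) >= 2L) subsets[[nm]] <- as.integer(classes[[nm]])
  }
  if (!is.null(subsets$relevant) && length(classes$entangled) >= 1L) {
    subsets[["relevant+entangled"]] <-
      sort(unique(c(subsets$relevant, as.integer(classes$entangled))))
  }
  battery <- subsetBattery(xHat, teL, subsets)
  df <- data.frame(subset = names(battery),
                   accuracy = vapply(battery, accuracy, numeric(1)),
                   n_comparisons = vapply(battery, nComparisons, integer(1)))
  out <- character(0)
  p <- .artifact(config, "decode", "decoded_latents.tsv"); writeMatrixTsv(xHat, p)
  out <- c(out, p)
  p <- .artifact(config, "decode", "subset_accuracy.tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(out, p)
  .writeManifest(config, "decode",
                 .artifact(config, "encode", "fit_W.tsv"), out, list())
}

.stage_stats <- function(config, seed) {
  teY <- readMatrixTsv(.requireArtifact(config, "simulate", "test_responses.tsv"))
  pred <- readMatrixTsv(.requireArtifact(config, "encode", "predicted_test.tsv"))
  rois <- .roiIndexList(config)
  rows <- list()
  for (nm in names(rois)) {
    pr <- permTestAboveChance(pred, teY, voxels = rois[[nm]],
                              resamples = config$resamples,
                              seed = deriveSeed(seed, match(nm, names(rois))))
    rows[[length(rows) + 1L]] <- data.frame(
      test = "above_chance", roi = nm, statistic = observedStat(pr),
      p = pValue(pr), tail = pr@tail, resamples = config$resamples)
  }
  if (all(c("OFA", "FFA") %in% names(rois))) {
    full <- spearmanColumns(pred, teY)
    pr <- permTestRoiDiff(full[rois$OFA], full[rois$FFA],
                          resamples = config$resamples,
                          seed = deriveSeed(seed, 99L))
    rows[[length(rows) + 1L]] <- data.frame(
      test = "roi_diff_OFA_FFA", roi = "OFA-FFA", statistic = observedStat(pr),
      p = pValue(pr), tail = pr@tail, resamples = config$resamples)
  }
  df <- do.call(rbind, rows)
  p <- .artifact(config, "stats", "permutation_tests.tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(config, "stats",
                 .artifact(config, "encode", "predicted_test.tsv"), p, list())
}

.stage_report <- function(config, seed) {
  stats <- .requireArtifact(config, "stats", "permutation_tests.tsv")
  profiles <- .requireArtifact(config, "prefmap", "roi_profiles.tsv")
  decode <- .requireArtifact(config, "decode", "subset_accuracy.tsv")
  scores <- .requireArtifact(config, "simulate", "voxel_scores.tsv")
  perVox <- .requireArtifact(config, "encode", "per_voxel_r.tsv")

  sel <- utils::read.delim(.requireArtifact(config, "roi", "selection.tsv"),
                           stringsAsFactors = FALSE)
  r <- readMatrixTsv(perVox)[, 1]
  rel <- readMatrixTsv(scores)[, "reliability"]
  enc <- do.call(rbind, lapply(split(sel, sel$parcel), function(d) {
    idx <- d$voxel[d$selected]
    data.frame(roi = d$parcel[1], n_voxels = length(idx),
               mean_r = mean(r[idx]), mean_reliability = mean(rel[idx]))
  }))
  out <- character(0)
  p <- .artifact(config, "report", "encoding_by_roi.tsv")
  utils::write.table(enc, p, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(out, p)
  for (f in c(stats, profiles, decode)) {
    p <- .artifact(config, "report", basename(f))
    file.copy(f, p, overwrite = TRUE)
    out <- c(out, p)
  }
  .writeManifest(config, "report", c(stats, profiles, decode), out, list())
}
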