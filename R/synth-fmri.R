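# Simulated voxel responses with known ground truth. The generative model is
# exactly the linear model assumed by the encoding GLM (per-presentation
# amplitude y = x' W* + b* + noise; or its HRF-convolved time-series mirror),
# so noiseless recovery is exact.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the usual canonical shape: response
#' peak near 6 s, undershoot near 16 s, undershoot ratio 1/6. Scaled to unit
#' peak.
#'
#' @param t Numeric vector of times in seconds (values < 0 return 0).
#' @param peak Time-to-peak shape parameter (gamma shape, rate 1).
#' @param undershoot Undershoot shape parameter.
#' @param ratio Undershoot amplitude ratio.
#' @return Numeric vector of HRF values.
#' @examples
#' h <- canonicalHrf(seq(0, 30, by = 0.5))
#' which.max(h)
#' @export
canonicalHrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- ifelse(t < 0, 0,
              stats::dgamma(t, shape = peak, rate = 1) -
                ratio * stats::dgamma(t, shape = undershoot, rate = 1))
  dense <- seq(0, 32, by = 0.01)
  mx <- max(stats::dgamma(dense, shape = peak, rate = 1) -
              ratio * stats::dgamma(dense, shape = undershoot, rate = 1))
  h / mx
}

#' Construct a ground-truth encoding
#'
#' Draws a latent-to-voxel weight matrix with optional single-dimension
#' voxels, per-run drift slopes, per-run motion coefficients and a per-voxel
#' noise scale.
#'
#' @param latentDim Number of latent dimensions driving the voxels.
#' @param nVoxels Number of voxels.
#' @param nRuns Number of runs (for the drift/motion nuisance structure).
#' @param singleDimVoxels Count of voxels driven by exactly one latent
#'   dimension (assigned cyclically over dimensions); the rest are dense.
#' @param noiseSd Per-voxel noise sd (scalar recycled, or length nVoxels).
#'   Use [noiseSdForSnr()] to set it relative to the signal.
#' @param biasSd Spread of the per-voxel face bias.
#' @param seed Integer seed.
#' @return A \linkS4class{GroundTruthEncoding}.
#' @examples
#' truth <- makeGroundTruth(latentDim = 4, nVoxels = 10, seed = 1)
#' dim(encodingWeights(truth))
#' @export
makeGroundTruth <- function(latentDim, nVoxels, nRuns = 1L, singleDimVoxels = 0L,
                            noiseSd = 1, biasSd = 1, seed = 1L) {
  stopifnot(latentDim >= 1, nVoxels >= 1, singleDimVoxels <= nVoxels)
  withSeed(seed, {
    W <- matrix(rnorm(latentDim * nVoxels), latentDim, nVoxels)
    plan <- rep(list(seq_len(latentDim)), nVoxels)
    if (singleDimVoxels > 0L) {
      dims <- rep_len(seq_len(latentDim), singleDimVoxels)
      for (j in seq_len(singleDimVoxels)) {
        keep <- W[dims[j], j]
        W[, j] <- 0
        # preserve the signal scale a dense voxel would have
        W[dims[j], j] <- sign(keep) * sqrt(latentDim) * max(abs(keep), 0.5)
        plan[[j]] <- dims[j]
      }
    }
    new("GroundTruthEncoding",
        W = W,
        b = rnorm(nVoxels, sd = biasSd),
        driftCoefs = matrix(rnorm(nRuns * nVoxels, sd = 0.5), nRuns, nVoxels),
        motionCoefs = matrix(rnorm(3L * nRuns * nVoxels, sd = 0.3), 3L * nRuns, nVoxels),
        noiseSd = rep_len(noiseSd, nVoxels),
        sparsityPlan = plan)
  })
}

#' Noise sd yielding a target per-trial SNR
#'
#' Returns per-voxel noise standard deviations equal to
#' sd(signal) / snr, where the signal is x' W* over the supplied latents.
#'
#' @param truth A \linkS4class{GroundTruthEncoding}.
#' @param latents Stimulus x latent-dimension matrix used to measure the
#'   signal spread.
#' @param snr Target per-trial signal-to-noise ratio.
#' @return Numeric vector of per-voxel noise sds.
#' @export
noiseSdForSnr <- function(truth, latents, snr) {
  sig <- latents %*% encodingWeights(truth)
  apply(sig, 2, stats::sd) / snr
}

#' Replace the noise scale of a ground truth
#'
#' @param truth A \linkS4class{GroundTruthEncoding}.
#' @param noiseSd Scalar or per-voxel noise sd.
#' @return The modified truth.
#' @export
setNoiseSd <- function(truth, noiseSd) {
  truth@noiseSd <- rep_len(noiseSd, ncol(truth@W))
  validObject(truth)
  truth
}

#' Simulate repeat-averaged voxel responses
#'
#' Each presentation of stimulus x yields y = x' W* + b* + noise with
#' independent Gaussian noise per voxel per presentation. Training faces are
#' presented once; each test face is presented `repeats` times and the
#' repeats are averaged (and retained for reliability analyses).
#'
#' @param trainLatents Training-stimulus x latent matrix.
#' @param testLatents Test-stimulus x latent matrix (20 rows in the standard
#'   design).
#' @param truth A \linkS4class{GroundTruthEncoding}; latent columns of the
#'   inputs must match its weight rows.
#' @param repeats Presentations per test face (>= 1).
#' @param seed Integer seed.
#' @return A \linkS4class{FaceVoxelExperiment}.
#' @examples
#' truth <- makeGroundTruth(3, 8, noiseSd = 0, seed = 1)
#' X <- matrix(rnorm(30), 10, 3)
#' Xt <- matrix(rnorm(9), 3, 3)
#' fve <- simulateVoxelResponses(X, Xt, truth, repeats = 2, seed = 1)
#' dim(testResponses(fve))
#' @export
simulateVoxelResponses <- function(trainLatents, testLatents, truth,
                                   repeats = 50L, seed = 1L) {
  assertMatrix(trainLatents); assertMatrix(testLatents)
  W <- encodingWeights(truth)
  if (ncol(trainLatents) != nrow(W) || ncol(testLatents) != nrow(W)) {
    stop("latent columns must match the ground-truth weight rows")
  }
  repeats <- as.integer(repeats)
  stopifnot(repeats >= 1L)
  v <- ncol(W)
  b <- faceBias(truth)
  sdv <- noiseSd(truth)
  withSeed(seed, {
    trainMean <- trainLatents %*% W + matrix(b, nrow(trainLatents), v, byrow = TRUE)
    trainY <- trainMean + matrix(rnorm(length(trainMean)), nrow(trainMean)) *
      matrix(sdv, nrow(trainMean), v, byrow = TRUE)
    testMean <- testLatents %*% W + matrix(b, nrow(testLatents), v, byrow = TRUE)
    reps <- array(0, c(nrow(testLatents), v, repeats))
    for (r in seq_len(repeats)) {
      reps[, , r] <- testMean + matrix(rnorm(length(testMean)), nrow(testMean)) *
        matrix(sdv, nrow(testMean), v, byrow = TRUE)
    }
    testY <- apply(reps, c(1, 2), mean)

    nTr <- nrow(trainY); nTe <- nrow(testY)
    ids <- c(sprintf("train_%04d", seq_len(nTr)), sprintf("test_%02d", seq_len(nTe)))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(response = t(rbind(trainY, testY))),
      colData = S4Vectors::DataFrame(
        stimulus_id = ids,
        set = rep(c("train", "test"), c(nTr, nTe)),
        row.names = ids),
      rowData = S4Vectors::DataFrame(
        voxel_id = sprintf("vox_%04d", seq_len(v)),
        noise_sd = sdv,
        single_dim = vapply(sparsityPlan(truth), function(p)
          if (length(p) == 1L) p else NA_integer_, integer(1))))
    new("FaceVoxelExperiment", se, testRepeats = reps)
  })
}

# Smooth random-walk motion traces (3 axes), centered per run.
.motionTraces <- function(nTime, runIndex) {
  m <- matrix(0, nTime, 3)
  for (r in unique(runIndex)) {
    idx <- which(runIndex == r)
    for (a in 1:3) {
      w <- cumsum(rnorm(length(idx), sd = 0.05))
      w <- stats::filter(w, rep(1 / 5, 5), sides = 2)
      w[is.na(w)] <- 0
      m[idx, a] <- w - mean(w)
    }
  }
  m
}

#' Simulate an event-related fMRI session
#'
#' Presents every training face once and every test face `testRepeats` times
#' in randomized order, one event every 3 seconds (1 s stimulus, 2 s ISI).
#' The voxel signal is the HRF-convolved, latent-weighted impulse train plus
#' a constant baseline b*, per-run linear drift, motion-trace contributions
#' and white noise — exactly the model an hrf-mode encoding design assumes.
#'
#' @inheritParams simulateVoxelResponses
#' @param testRepeats Presentations per test face in the session.
#' @param TR Repetition time in seconds (> 0).
#' @param nRuns Number of runs; must match the truth's nuisance structure.
#' @return A \linkS4class{SimulatedSession}.
#' @export
simulateTimeseries <- function(trainLatents, testLatents, truth, TR = 2,
                               testRepeats = 5L, nRuns = NULL, seed = 1L) {
  assertMatrix(trainLatents); assertMatrix(testLatents)
  if (TR <= 0) stop("TR must be positive")
  W <- encodingWeights(truth)
  if (ncol(trainLatents) != nrow(W)) stop("latent columns must match weight rows")
  if (is.null(nRuns)) nRuns <- nrow(truth@driftCoefs)
  stopifnot(nRuns == nrow(truth@driftCoefs))
  nTr <- nrow(trainLatents); nTe <- nrow(testLatents)
  v <- ncol(W)

  withSeed(seed, {
    stim <- c(sprintf("train_%04d", seq_len(nTr)),
              rep(sprintf("test_%02d", seq_len(nTe)), each = testRepeats))
    stim <- sample(stim)
    nEv <- length(stim)
    perRun <- ceiling(nEv / nRuns)
    run <- rep(seq_len(nRuns), each = perRun)[seq_len(nEv)]
    onset <- unlist(lapply(seq_len(nRuns), function(r) {
      3 * (seq_len(sum(run == r)) - 1)
    }))
    events <- data.frame(onset = onset, duration = 1, stimulus_id = stim, run = run,
                         stringsAsFactors = FALSE)
    runLenSec <- vapply(seq_len(nRuns), function(r) {
      max(events$onset[events$run == r]) + 3 + 18   # post-stimulus tail
    }, numeric(1))
    runLenTR <- ceiling(runLenSec / TR)
    runIndex <- rep(seq_len(nRuns), runLenTR)
    nTime <- length(runIndex)
    motion <- .motionTraces(nTime, runIndex)

    rownames(trainLatents) <- sprintf("train_%04d", seq_len(nTr))
    design <- buildDesign(trainLatents, testIds = sprintf("test_%02d", seq_len(nTe)),
                          mode = "hrf", events = events, TR = TR,
                          runIndex = runIndex, motion = motion)
    roles <- columnRoles(design)
    B <- matrix(0, ncol(designValues(design)), v)
    B[grepl("^latent\\(", roles), ] <- W
    B[roles == "face_bias", ] <- faceBias(truth)
    testAmp <- testLatents %*% W
    B[grepl("^test_image\\(", roles), ] <- testAmp
    for (r in seq_len(nRuns)) {
      B[roles == sprintf("drift(%d)", r), ] <- truth@driftCoefs[r, ]
      for (a in 1:3) {
        B[roles == sprintf("motion(%d,%d)", a, r), ] <- truth@motionCoefs[3 * (r - 1) + a, ]
      }
    }
    Y <- designValues(design) %*% B
    sdv <- noiseSd(truth)
    Y <- Y + matrix(rnorm(length(Y)), nrow(Y)) * matrix(sdv, nrow(Y), v, byrow = TRUE)

    new("SimulatedSession",
        series = Y, events = events, motion = motion,
        runIndex = as.integer(runIndex), TR = TR,
        averagedTest = testAmp,
        averagedTrain = trainLatents %*% W)
  })
}

#' Simulate a face-object localizer statistic
#'
#' Draws a per-voxel selectivity statistic (larger = more face-selective):
#' standard normal for non-face voxels, shifted by `shift` standard deviations
#' for voxels in the face mask.
#'
#' @param faceMask Logical vector marking the truly face-selective voxels.
#' @param shift Shift in sd units applied to masked voxels.
#' @param parcelLabels Optional character vector of parcel ids (recycled NA
#'   if missing).
#' @param seed Integer seed.
#' @return A \linkS4class{LocalizerStats}.
#' @export
simulateLocalizer <- function(faceMask, shift = 3, parcelLabels = NULL, seed = 1L) {
  n <- length(faceMask)
  if (is.null(parcelLabels)) parcelLabels <- rep(NA_character_, n)
  if (length(parcelLabels) != n) stop("parcelLabels must match the voxel count")
  withSeed(seed, {
    stat <- rnorm(n) + shift * as.numeric(faceMask)
    new("LocalizerStats", selectivityStat = stat,
        parcelLabels = as.character(parcelLabels))
  })
}
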