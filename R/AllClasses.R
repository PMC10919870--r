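#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd rnorm runif cor qnorm quantile coef
#' @importFrom utils write.table read.delim head tail
NULL

#' Ground-truth linear encoding used by the simulator
#'
#' Holds the generative weights that map latent factors to voxel responses,
#' together with the nuisance structure (per-run linear drift slopes, per-run
#' motion coefficients) and the per-voxel noise scale. Used both to generate
#' synthetic responses and as the reference in parameter-recovery tests.
#'
#' @slot W numeric matrix, latent dimensions x voxels.
#' @slot b numeric vector, per-voxel face bias.
#' @slot driftCoefs numeric matrix, runs x voxels (slope of the within-run
#'   linear drift).
#' @slot motionCoefs numeric matrix, (3 * runs) x voxels.
#' @slot noiseSd numeric vector, per-voxel noise standard deviation (> 0, or 0
#'   for noiseless simulations).
#' @slot sparsityPlan list, one integer vector per voxel giving the latent
#'   dimensions that drive it (all dims for dense voxels).
#' @exportClass GroundTruthEncoding
setClass("GroundTruthEncoding",
  representation(
    W = "matrix", b = "numeric", driftCoefs = "matrix",
    motionCoefs = "matrix", noiseSd = "numeric", sparsityPlan = "list"
  )
)

setValidity("GroundTruthEncoding", function(object) {
  msg <- character()
  v <- ncol(object@W)
  if (length(object@b) != v) msg <- c(msg, "length(b) must equal ncol(W)")
  if (ncol(object@driftCoefs) != v) msg <- c(msg, "driftCoefs columns must equal ncol(W)")
  if (ncol(object@motionCoefs) != v) msg <- c(msg, "motionCoefs columns must equal ncol(W)")
  if (nrow(object@motionCoefs) != 3 * nrow(object@driftCoefs)) {
    msg <- c(msg, "motionCoefs must have 3 rows per run")
  }
  if (length(object@noiseSd) != v) msg <- c(msg, "length(noiseSd) must equal ncol(W)")
  if (any(object@noiseSd < 0)) msg <- c(msg, "noiseSd must be non-negative")
  if (length(object@sparsityPlan) != v) msg <- c(msg, "sparsityPlan must have one entry per voxel")
  for (j in seq_len(v)) {
    dims <- object@sparsityPlan[[j]]
    if (any(dims < 1L) || any(dims > nrow(object@W))) {
      msg <- c(msg, sprintf("sparsityPlan for voxel %d has invalid dimension indices", j))
      break
    }
    if (length(dims) == 1L && sum(object@W[, j] != 0) > 1L) {
      msg <- c(msg, sprintf("single-dimension voxel %d has more than one nonzero weight", j))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic face dataset with known generative factors
#'
#' Container for procedurally rendered training and test faces together with
#' the factor values that generated them. Exactly 20 test faces are held,
#' mirroring the condition-rich single-presentation design the simulator
#' emulates (many training faces shown once, 20 test faces shown 40-60 times).
#'
#' @slot spec data.frame describing the generative factors (see
#'   [defaultFactorSpec()]).
#' @slot trainImages numeric array, nTrain x side x side, pixel values in
#'   [0, 1].
#' @slot trainFactors numeric matrix, nTrain x factors.
#' @slot testImages numeric array, 20 x side x side.
#' @slot testFactors numeric matrix, 20 x factors.
#' @slot testRepeats integer, nominal presentation count per test face
#'   (in [40, 60]).
#' @slot seed integer seed the dataset was drawn with.
#' @exportClass SyntheticFaceSet
setClass("SyntheticFaceSet",
  representation(
    spec = "data.frame", trainImages = "array", trainFactors = "matrix",
    testImages = "array", testFactors = "matrix", testRepeats = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticFaceSet", function(object) {
  msg <- character()
  k <- nrow(object@spec)
  if (ncol(object@trainFactors) != k) msg <- c(msg, "trainFactors columns must match factor spec")
  if (nrow(object@testFactors) != 20L || dim(object@testImages)[1] != 20L) {
    msg <- c(msg, "exactly 20 test faces are required")
  }
  if (object@testRepeats < 40L || object@testRepeats > 60L) {
    msg <- c(msg, "testRepeats must lie in [40, 60]")
  }
  rel <- which(object@spec$identityRelevant)
  if (length(rel) >= 1L) {
    d <- as.matrix(stats::dist(object@testFactors[, rel, drop = FALSE]))
    diag(d) <- Inf
    if (any(d < sqrt(.Machine$double.eps))) {
      msg <- c(msg, "test identities must be pairwise distinct in identity-relevant factor space")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Simulated voxel responses as a SummarizedExperiment
#'
#' Repeat-averaged responses for all stimuli, stored as a
#' \linkS4class{SummarizedExperiment} with voxels as rows and stimuli as
#' columns. `colData` records the stimulus id, set membership (train/test) and
#' the generative factor values; `rowData` records per-voxel metadata (noise
#' sd, sparsity class). The repeat-level responses to the 20 test faces are
#' kept in `testRepeats` (test stimuli x voxels x repeats) for split-half
#' reliability analyses.
#'
#' @exportClass FaceVoxelExperiment
setClass("FaceVoxelExperiment",
  contains = "SummarizedExperiment",
  representation(testRepeats = "array")
)

setValidity("FaceVoxelExperiment", function(object) {
  msg <- character()
  if (length(dim(object@testRepeats)) != 3L) {
    msg <- c(msg, "testRepeats must be a 3-d array (test stimuli x voxels x repeats)")
  } else {
    if (dim(object@testRepeats)[2] != nrow(object)) {
      msg <- c(msg, "testRepeats voxel axis must match the experiment rows")
    }
    nTest <- sum(SummarizedExperiment::colData(object)$set == "test")
    if (dim(object@testRepeats)[1] != nTest) {
      msg <- c(msg, "testRepeats stimulus axis must match the number of test stimuli")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Simulated fMRI session (time-series form)
#'
#' Event-related voxel time series generated by HRF convolution of
#' latent-weighted stimulus impulses plus per-run linear drift, motion-trace
#' contributions, a constant baseline, and white noise.
#'
#' @slot series numeric matrix, time points x voxels.
#' @slot events data.frame with columns onset, duration, stimulus_id, run
#'   (onsets in seconds).
#' @slot motion numeric matrix, time points x 3 (x, y, z traces).
#' @slot runIndex integer vector mapping each time point to its run.
#' @slot TR numeric, repetition time in seconds.
#' @slot averagedTest numeric matrix, 20 x voxels: noise-free presentation
#'   amplitudes of the test faces (x W* per image).
#' @slot averagedTrain numeric matrix, nTrain x voxels, analogous.
#' @exportClass SimulatedSession
setClass("SimulatedSession",
  representation(
    series = "matrix", events = "data.frame", motion = "matrix",
    runIndex = "integer", TR = "numeric", averagedTest = "matrix",
    averagedTrain = "matrix"
  )
)

setValidity("SimulatedSession", function(object) {
  msg <- character()
  if (nrow(object@motion) != nrow(object@series)) msg <- c(msg, "motion rows must match series rows")
  if (length(object@runIndex) != nrow(object@series)) msg <- c(msg, "runIndex must match series rows")
  if (object@TR <= 0) msg <- c(msg, "TR must be positive")
  dur <- tapply(seq_along(object@runIndex), object@runIndex, length)
  for (r in unique(object@events$run)) {
    lastOnset <- max(object@events$onset[object@events$run == r] +
                       object@events$duration[object@events$run == r])
    if (lastOnset > dur[[as.character(r)]] * object@TR) {
      msg <- c(msg, sprintf("events in run %s extend beyond the run duration", r))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-voxel localizer selectivity statistics
#'
#' @slot selectivityStat numeric vector, one statistic per voxel (larger =
#'   more face-selective).
#' @slot parcelLabels character vector of parcel ids (NA for unparcellated
#'   voxels).
#' @exportClass LocalizerStats
setClass("LocalizerStats",
  representation(selectivityStat = "numeric", parcelLabels = "character")
)

setValidity("LocalizerStats", function(object) {
  if (length(object@selectivityStat) != length(object@parcelLabels)) {
    "selectivityStat and parcelLabels must have equal length"
  } else TRUE
})

#' GLM design matrix with tagged column roles
#'
#' @slot values numeric matrix, observations x regressors.
#' @slot columnRoles character vector tagging each column as one of
#'   `latent(d)`, `test_image(i)`, `face_bias`, `drift(run)`,
#'   `motion(axis,run)`.
#' @slot mode `"amplitude"` (rows are presentations) or `"hrf"` (rows are
#'   time points).
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(values = "matrix", columnRoles = "character", mode = "character")
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (length(object@columnRoles) != ncol(object@values)) {
    msg <- c(msg, "one column role per design column is required")
  }
  if (sum(object@columnRoles == "face_bias") != 1L) {
    msg <- c(msg, "exactly one face_bias column is required")
  }
  if (!object@mode %in% c("amplitude", "hrf")) msg <- c(msg, "mode must be 'amplitude' or 'hrf'")
  if (length(msg)) msg else TRUE
})

#' Fitted voxelwise encoding model
#'
#' @slot W numeric matrix, latent dimensions x voxels (the learned beta
#'   weights for the latent regressors).
#' @slot b numeric vector, per-voxel face bias.
#' @slot nuisance numeric matrix of the remaining coefficients (test-image
#'   indicators, drift, motion), rows named by role.
#' @slot mode design mode the fit came from.
#' @exportClass EncodingFit
setClass("EncodingFit",
  representation(W = "matrix", b = "numeric", nuisance = "matrix", mode = "character")
)

setValidity("EncodingFit", function(object) {
  msg <- character()
  if (length(object@b) != ncol(object@W)) msg <- c(msg, "length(b) must equal ncol(W)")
  if (ncol(object@nuisance) && ncol(object@nuisance) != ncol(object@W)) {
    msg <- c(msg, "nuisance columns must equal ncol(W)")
  }
  if (!all(is.finite(object@W)) || !all(is.finite(object@b))) msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' Encoding prediction evaluation
#'
#' @slot predicted numeric matrix, test stimuli x voxels.
#' @slot perVoxelR numeric vector of Spearman correlations across test
#'   stimuli.
#' @slot constant logical vector flagging voxels whose predicted or observed
#'   response was constant (their r is recorded as 0).
#' @slot roiMeans numeric vector of per-ROI mean correlations.
#' @exportClass PredictionResult
setClass("PredictionResult",
  representation(
    predicted = "matrix", perVoxelR = "numeric", constant = "logical",
    roiMeans = "numeric"
  )
)

setValidity("PredictionResult", function(object) {
  if (any(object@perVoxelR < -1 - 1e-12 | object@perVoxelR > 1 + 1e-12)) {
    "per-voxel correlations must lie in [-1, 1]"
  } else TRUE
})

#' Voxel selection by combined selectivity and reliability
#'
#' @slot vS numeric, z-scored selectivity.
#' @slot vR numeric, z-scored reliability.
#' @slot v numeric, the selection metric vS + vR.
#' @slot selected logical flags.
#' @slot parcel character parcel ids.
#' @exportClass VoxelSelection
setClass("VoxelSelection",
  representation(
    vS = "numeric", vR = "numeric", v = "numeric", selected = "logical",
    parcel = "character"
  )
)

setValidity("VoxelSelection", function(object) {
  n <- length(object@v)
  if (length(object@vS) != n || length(object@vR) != n ||
      length(object@selected) != n || length(object@parcel) != n) {
    return("all per-voxel slots must have equal length")
  }
  if (max(abs(object@v - (object@vS + object@vR))) > 1e-10) {
    return("v must equal vS + vR elementwise")
  }
  TRUE
})

#' Winner-take-all preference map
#'
#' @slot perDimR numeric matrix, voxels x dimensions, Spearman correlation of
#'   the single-dimension prediction with the observed response.
#' @slot winner integer vector, best-predicting dimension per voxel (NA when
#'   the best r is <= 0: winner-take-all on noise is meaningless).
#' @slot bestR numeric vector, the winning correlation per voxel.
#' @slot roiProfiles numeric matrix, ROIs x dimensions, mean r per ROI.
#' @exportClass PreferenceMap
setClass("PreferenceMap",
  representation(
    perDimR = "matrix", winner = "integer", bestR = "numeric",
    roiProfiles = "matrix"
  )
)

setValidity("PreferenceMap", function(object) {
  msg <- character()
  if (length(object@winner) != nrow(object@perDimR)) msg <- c(msg, "one winner per voxel required")
  if (any(object@perDimR < -1 - 1e-12 | object@perDimR > 1 + 1e-12)) {
    msg <- c(msg, "correlations must lie in [-1, 1]")
  }
  ok <- !is.na(object@winner)
  if (any(ok)) {
    mx <- apply(object@perDimR[ok, , drop = FALSE], 1, max)
    if (max(abs(object@perDimR[cbind(which(ok), object@winner[ok])] - mx)) > 1e-12) {
      msg <- c(msg, "winner must be the argmax dimension of perDimR")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pairwise identity-decoding result
#'
#' @slot accuracy numeric in [0, 1].
#' @slot nComparisons integer count of scored (target, foil) pairs; with the
#'   standard 20 test faces this is 20 * 19 = 380.
#' @slot subsetName character label of the dimension subset used.
#' @slot perPair data.frame of per-pair outcomes (target, foil, score).
#' @exportClass DecodingResult
setClass("DecodingResult",
  representation(
    accuracy = "numeric", nComparisons = "integer", subsetName = "character",
    perPair = "data.frame"
  )
)

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 1) msg <- c(msg, "accuracy must lie in [0, 1]")
  if (nrow(object@perPair) &&
      abs(object@accuracy - sum(object@perPair$score) / object@nComparisons) > 1e-12) {
    msg <- c(msg, "accuracy must equal mean per-pair score")
  }
  if (length(msg)) msg else TRUE
})

#' Permutation-test result
#'
#' @slot observed numeric, the observed statistic.
#' @slot nullSamples numeric vector of resampled null statistics.
#' @slot pValue numeric in (0, 1], add-one corrected.
#' @slot tail `"one"` or `"two"`.
#' @slot level `"individual"` or `"group"`.
#' @slot seed integer seed used for the resampling.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(
    observed = "numeric", nullSamples = "numeric", pValue = "numeric",
    tail = "character", level = "character", seed = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@pValue <= 0 || object@pValue > 1) msg <- c(msg, "pValue must lie in (0, 1]")
  if (!object@tail %in% c("one", "two")) msg <- c(msg, "tail must be 'one' or 'two'")
  if (!object@level %in% c("individual", "group")) msg <- c(msg, "level must be 'individual' or 'group'")
  if (length(msg)) msg else TRUE
})

#' Trained variational autoencoder
#'
#' @slot params named list of encoder/decoder weight matrices and bias
#'   vectors.
#' @slot discriminator named list of total-correlation discriminator
#'   parameters (empty for plain beta-VAE models).
#' @slot config the model configuration list (see [vaeConfig()]).
#' @slot trainingLog data.frame with one row per epoch: reconstruction, KL,
#'   TC estimate and held-out reconstruction error.
#' @exportClass VaeModel
setClass("VaeModel",
  representation(
    params = "list", discriminator = "list", config = "list",
    trainingLog = "data.frame"
  )
)

setValidity("VaeModel", function(object) {
  msg <- character()
  if (nrow(object@trainingLog) &&
      nrow(object@trainingLog) != object@config$epochs) {
    msg <- c(msg, "trainingLog must contain exactly `epochs` records")
  }
  if (nrow(object@trainingLog) &&
      !all(is.finite(as.matrix(object@trainingLog[
        , c("reconstruction", "kl", "heldoutReconstruction")])))) {
    msg <- c(msg, "training losses must be finite")
  }
  if (length(msg)) msg else TRUE
})
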