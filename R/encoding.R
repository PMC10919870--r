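# Voxelwise encoding GLM. Latent values enter as weighted (parametrically
# modulated) regressors; test faces get indicator regressors so their
# single-trial structure does not bias the latent weights; a face bias term
# and per-run drift/motion nuisance complete the design.

#' Build an encoding design matrix
#'
#' In `"amplitude"` mode rows are presentations: training rows carry the
#' stimulus's latent values in the latent columns, test rows carry an
#' indicator for their image, and every row has face_bias = 1. In `"hrf"`
#' mode rows are time points: each latent column is the HRF-convolved impulse
#' train whose event heights are that stimulus's latent value (test events
#' excluded), each test-image column is the convolved unit impulse train of
#' that image's presentations, face_bias is the constant baseline column, the
#' drift column is linear (centered) within each run and zero elsewhere, and
#' motion columns carry the centered motion traces per run.
#'
#' @param trainLatents Training-stimulus x latent matrix; in hrf mode its
#'   rownames must match the training stimulus ids in `events`.
#' @param testIds Character vector of test stimulus ids (indicator columns).
#' @param mode `"amplitude"` or `"hrf"`.
#' @param run Amplitude mode: optional integer run per presentation row.
#' @param motion Amplitude mode: optional presentations x 3 motion values;
#'   hrf mode: time points x 3 motion traces.
#' @param events Hrf mode: data.frame with onset (s), duration, stimulus_id,
#'   run.
#' @param TR Hrf mode: repetition time in seconds.
#' @param runIndex Hrf mode: integer run id per time point.
#' @param hrf Function of time (s) returning the hemodynamic kernel; sampled
#'   on the TR grid with 32 s of support.
#' @return A \linkS4class{DesignMatrix}.
#' @examples
#' X <- matrix(rnorm(20), 10, 2)
#' d <- buildDesign(X, testIds = c("t1", "t2"))
#' columnRoles(d)
#' @export
buildDesign <- function(trainLatents, testIds = character(),
                        mode = c("amplitude", "hrf"),
                        run = NULL, motion = NULL,
                        events = NULL, TR = NULL, runIndex = NULL,
                        hrf = canonicalHrf) {
  mode <- match.arg(mode)
  assertMatrix(trainLatents)
  k <- ncol(trainLatents)
  latentRoles <- sprintf("latent(%d)", seq_len(k))
  testRoles <- if (length(testIds)) sprintf("test_image(%d)", seq_along(testIds)) else character()

  if (mode == "amplitude") {
    nTr <- nrow(trainLatents); nTe <- length(testIds)
    n <- nTr + nTe
    X <- matrix(0, n, k + nTe + 1L)
    X[seq_len(nTr), seq_len(k)] <- trainLatents
    if (nTe) X[nTr + seq_len(nTe), k + seq_len(nTe)] <- diag(nTe)
    X[, k + nTe + 1L] <- 1
    roles <- c(latentRoles, testRoles, "face_bias")
    if (!is.null(run)) {
      stopifnot(length(run) == n)
      for (r in sort(unique(run))) {
        idx <- which(run == r)
        d <- numeric(n)
        d[idx] <- seq_along(idx) - mean(seq_along(idx))
        X <- cbind(X, d)
        roles <- c(roles, sprintf("drift(%d)", r))
        if (!is.null(motion)) {
          stopifnot(nrow(motion) == n, ncol(motion) == 3L)
          for (a in 1:3) {
            m <- numeric(n)
            m[idx] <- motion[idx, a] - mean(motion[idx, a])
            X <- cbind(X, m)
            roles <- c(roles, sprintf("motion(%d,%d)", a, r))
          }
        }
      }
    }
    colnames(X) <- NULL
    return(new("DesignMatrix", values = X, columnRoles = roles, mode = "amplitude"))
  }

  # hrf mode
  stopifnot(!is.null(events), !is.null(TR), !is.null(runIndex))
  if (is.null(rownames(trainLatents))) stop("hrf mode requires rownames on trainLatents")
  missing <- setdiff(setdiff(unique(events$stimulus_id), testIds), rownames(trainLatents))
  if (length(missing)) {
    stop("no latent row for stimulus: ", paste(head(missing, 3), collapse = ", "))
  }
  nTime <- length(runIndex)
  runs <- sort(unique(runIndex))
  kernel <- hrf(seq(0, 32, by = TR))

  convolveRuns <- function(impulse) {
    out <- numeric(nTime)
    for (r in runs) {
      idx <- which(runIndex == r)
      conv <- stats::convolve(impulse[idx], rev(kernel), type = "open")
      out[idx] <- conv[seq_along(idx)]
    }
    out
  }
  eventBin <- pmin(nTime, unlist(lapply(runs, function(r) {
    which(runIndex == r)[1] - 1L + floor(events$onset[events$run == r] / TR) + 1L
  })))
  evOrder <- unlist(lapply(runs, function(r) which(events$run == r)))
  stimAt <- events$stimulus_id[evOrder]

  nCols <- k + length(testIds) + 1L + length(runs) * (1L + if (!is.null(motion)) 3L else 0L)
  X <- matrix(0, nTime, nCols)
  roles <- character(nCols)
  col <- 0L
  for (d in seq_len(k)) {
    impulse <- numeric(nTime)
    isTrain <- stimAt %in% rownames(trainLatents)
    amp <- ifelse(isTrain, trainLatents[match(stimAt, rownames(trainLatents)), d], 0)
    amp[is.na(amp)] <- 0
    for (i in seq_along(eventBin)) impulse[eventBin[i]] <- impulse[eventBin[i]] + amp[i]
    col <- col + 1L
    X[, col] <- convolveRuns(impulse)
    roles[col] <- latentRoles[d]
  }
  for (i in seq_along(testIds)) {
    impulse <- numeric(nTime)
    hit <- which(stimAt == testIds[i])
    for (j in hit) impulse[eventBin[j]] <- impulse[eventBin[j]] + 1
    col <- col + 1L
    X[, col] <- convolveRuns(impulse)
    roles[col] <- testRoles[i]
  }
  col <- col + 1L
  X[, col] <- 1
  roles[col] <- "face_bias"
  for (r in runs) {
    idx <- which(runIndex == r)
    d <- numeric(nTime)
    d[idx] <- seq_along(idx) - mean(seq_along(idx))
    col <- col + 1L
    X[, col] <- d
    roles[col] <- sprintf("drift(%d)", r)
    if (!is.null(motion)) {
      for (a in 1:3) {
        m <- numeric(nTime)
        m[idx] <- motion[idx, a] - mean(motion[idx, a])
        col <- col + 1L
        X[, col] <- m
        roles[col] <- sprintf("motion(%d,%d)", a, r)
      }
    }
  }
  new("DesignMatrix", values = X, columnRoles = roles, mode = "hrf")
}

#' Fit the encoding GLM by ordinary least squares
#'
#' Per-voxel OLS of the responses on the design. With a rank-deficient design
#' a warning is raised and the minimum-norm (pseudo-inverse) solution is
#' returned instead.
#'
#' @param design A \linkS4class{DesignMatrix}.
#' @param responses Observations x voxels matrix (presentations in amplitude
#'   mode, time points in hrf mode).
#' @return An \linkS4class{EncodingFit}.
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' d <- buildDesign(X)
#' W <- matrix(c(1, -1), 2, 1)
#' y <- X %*% W + 0.5
#' fit <- fitEncodingGlm(d, y)
#' encodingWeights(fit)
#' @export
fitEncodingGlm <- function(design, responses) {
  stopifnot(is(design, "DesignMatrix"))
  responses <- as.matrix(responses)
  X <- designValues(design)
  if (nrow(X) != nrow(responses)) {
    stop("design rows (", nrow(X), ") must match response rows (", nrow(responses), ")")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("design is rank deficient; returning the minimum-norm solution")
    coefs <- MASS::ginv(X) %*% responses
  } else {
    coefs <- qr.coef(qrX, responses)
  }
  roles <- columnRoles(design)
  isLatent <- grepl("^latent\\(", roles)
  isBias <- roles == "face_bias"
  nuis <- coefs[!isLatent & !isBias, , drop = FALSE]
  rownames(nuis) <- roles[!isLatent & !isBias]
  new("EncodingFit",
      W = coefs[isLatent, , drop = FALSE],
      b = as.numeric(coefs[isBias, ]),
      nuisance = nuis,
      mode = designMode(design))
}

#' Predict held-out test responses
#'
#' ŷ = X_test W + b; nuisance coefficients are excluded.
#'
#' @param fit An \linkS4class{EncodingFit}.
#' @param testLatents Test-stimulus x latent matrix.
#' @return Test-stimulus x voxel matrix of predicted responses.
#' @export
predictTestResponses <- function(fit, testLatents) {
  assertMatrix(testLatents)
  W <- encodingWeights(fit)
  if (ncol(testLatents) != nrow(W)) stop("latent dimension mismatch")
  testLatents %*% W + matrix(faceBias(fit), nrow(testLatents), ncol(W), byrow = TRUE)
}

#' Evaluate encoding predictions with Spearman correlation
#'
#' Correlates predicted with observed responses across test stimuli,
#' per voxel. Voxels with a constant predicted or observed vector get r = 0
#' and are flagged.
#'
#' @param predicted,observed Test-stimulus x voxel matrices.
#' @param roi Optional ROI structure: either a named list of voxel index
#'   vectors or a per-voxel label vector; per-ROI mean correlations are
#'   reported.
#' @return A \linkS4class{PredictionResult}.
#' @export
evaluateEncoding <- function(predicted, observed, roi = NULL) {
  assertMatrix(predicted); assertMatrix(observed)
  if (!all(dim(predicted) == dim(observed))) stop("predicted/observed shapes differ")
  r <- spearmanColumns(predicted, observed)
  const <- attr(r, "constant")
  attributes(r) <- NULL
  roiM <- numeric(0)
  if (!is.null(roi)) {
    if (is.list(roi)) {
      roiM <- vapply(roi, function(idx) mean(r[idx]), numeric(1))
    } else {
      stopifnot(length(roi) == ncol(predicted))
      roiM <- vapply(split(r, roi), mean, numeric(1))
    }
  }
  new("PredictionResult", predicted = predicted, perVoxelR = r,
      constant = const, roiMeans = roiM)
}

#' Split-half reliability of repeated test presentations
#'
#' Randomly splits the repeats of each test face into two halves, averages
#' each half, correlates the halves across test faces (Spearman, per voxel),
#' and averages over `nSplits` random splits. This is the effective noise
#' ceiling of the encoding analysis.
#'
#' @param repeatResponses 3-d array, test stimuli x voxels x repeats (>= 2
#'   repeats), or a \linkS4class{FaceVoxelExperiment}.
#' @param nSplits Number of random splits to average over.
#' @param seed Integer seed.
#' @return Numeric vector of per-voxel reliabilities.
#' @export
splitHalfReliability <- function(repeatResponses, nSplits = 100L, seed = 1L) {
  if (is(repeatResponses, "FaceVoxelExperiment")) {
    repeatResponses <- testRepeatArray(repeatResponses)
  }
  d <- dim(repeatResponses)
  if (length(d) != 3L) stop("expected a stimuli x voxels x repeats array")
  R <- d[3]
  if (R < 2L) stop("at least 2 repeats per test face are required")
  half <- R %/% 2L
  withSeed(seed, {
    acc <- matrix(0, nSplits, d[2])
    for (s in seq_len(nSplits)) {
      idx <- sample(R, half)
      a <- apply(repeatResponses[, , idx, drop = FALSE], c(1, 2), mean)
      b <- apply(repeatResponses[, , -idx, drop = FALSE], c(1, 2), mean)
      r <- spearmanColumns(a, b)
      attributes(r) <- NULL
      acc[s, ] <- r
    }
    colMeans(acc)
  })
}
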