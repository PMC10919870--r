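# Preference mapping: predict held-out responses from one latent dimension at
# a time, and label each voxel by its best-predicting dimension
# (winner-take-all).

#' Predict test responses from a single latent dimension
#'
#' ŷ_d = x_d w_d + b: only dimension d's row of the weight matrix
#' contributes, plus the face bias (rank correlations are bias-invariant, but
#' the bias is included so exported predictions are on the response scale).
#'
#' @param fit An \linkS4class{EncodingFit}.
#' @param testLatents Test-stimulus x latent matrix.
#' @param d Dimension index.
#' @return Test-stimulus x voxel matrix.
#' @export
singleDimPredict <- function(fit, testLatents, d) {
  assertMatrix(testLatents)
  W <- encodingWeights(fit)
  if (d < 1 || d > nrow(W)) stop("invalid dimension index")
  testLatents[, d, drop = FALSE] %*% W[d, , drop = FALSE] +
    matrix(faceBias(fit), nrow(testLatents), ncol(W), byrow = TRUE)
}

#' Winner-take-all preference map and ROI preference profiles
#'
#' Computes the per-voxel Spearman correlation between each single-dimension
#' prediction and the observed test responses, assigns each voxel's winner as
#' the dimension with the highest correlation (ties broken by the lowest
#' dimension index; voxels whose best r is <= 0 get no winner), and averages
#' per-dimension correlations within each ROI.
#'
#' @param fit An \linkS4class{EncodingFit}.
#' @param testLatents Test-stimulus x latent matrix.
#' @param observed Test-stimulus x voxel matrix of observed responses.
#' @param roi Optional named list of voxel index vectors, or a per-voxel
#'   label vector.
#' @return A \linkS4class{PreferenceMap}.
#' @export
preferenceProfile <- function(fit, testLatents, observed, roi = NULL) {
  assertMatrix(observed)
  W <- encodingWeights(fit)
  nDim <- nrow(W); nVox <- ncol(W)
  if (ncol(observed) != nVox) stop("observed voxel count must match the fit")
  perDim <- matrix(0, nVox, nDim)
  for (d in seq_len(nDim)) {
    pred <- singleDimPredict(fit, testLatents, d)
    r <- spearmanColumns(pred, observed)
    attributes(r) <- NULL
    perDim[, d] <- r
  }
  winner <- max.col(perDim, ties.method = "first")
  bestR <- perDim[cbind(seq_len(nVox), winner)]
  winner[bestR <= 0] <- NA_integer_
  roiP <- matrix(numeric(0), 0, nDim)
  if (!is.null(roi)) {
    if (!is.list(roi)) {
      stopifnot(length(roi) == nVox)
      roi <- split(seq_len(nVox), roi)
    }
    roiP <- t(vapply(roi, function(idx) colMeans(perDim[idx, , drop = FALSE]),
                     numeric(nDim)))
    if (is.null(dim(roiP))) roiP <- matrix(roiP, nrow = length(roi))
    rownames(roiP) <- names(roi)
  }
  new("PreferenceMap", perDimR = perDim, winner = as.integer(winner),
      bestR = bestR, roiProfiles = roiP)
}
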