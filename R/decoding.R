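# Pseudo-inverse identity decoding: invert the fitted encoding map to recover
# latent vectors from voxel responses, then score facial identity with the
# pairwise foil procedure.

#' Decode latent vectors from voxel responses
#'
#' x̂ = pinv(W) applied to (y - b): each response row, minus the face bias,
#' is mapped back through the Moore-Penrose pseudo-inverse of the learned
#' weight matrix. With noiseless responses and at least as many voxels as
#' dimensions this recovers the true latents exactly.
#'
#' @param fit An \linkS4class{EncodingFit} (or a
#'   \linkS4class{GroundTruthEncoding}).
#' @param y Test-stimulus x voxel response matrix.
#' @return Test-stimulus x latent matrix of decoded latents.
#' @examples
#' W <- matrix(rnorm(12), 3, 4)
#' x <- matrix(rnorm(6), 2, 3)
#' fit <- new("EncodingFit", W = W, b = rep(1, 4),
#'            nuisance = matrix(0, 0, 4), mode = "amplitude")
#' xhat <- decodeLatents(fit, x %*% W + 1)
#' max(abs(xhat - x))
#' @export
decodeLatents <- function(fit, y) {
  assertMatrix(y)
  W <- encodingWeights(fit)
  b <- faceBias(fit)
  if (ncol(y) != ncol(W)) stop("voxel axes of the fit and responses must match")
  if (ncol(W) < nrow(W)) {
    warning("fewer voxels than latent dimensions: decoding is underdetermined")
  }
  (y - matrix(b, nrow(y), ncol(y), byrow = TRUE)) %*% MASS::ginv(W)
}

#' Pairwise identity-decoding accuracy with foils
#'
#' For every ordered (target, foil) pair of distinct test faces, the decoding
#' is correct when the decoded latent vector of the target correlates more
#' strongly with the target's true latents than with the foil's true latents
#' (restricted to the chosen dimension subset). Ties score 0.5. With the
#' standard 20 test faces this yields 20 * 19 = 380 comparisons.
#'
#' @param xHat Decoded test-stimulus x latent matrix.
#' @param xTrue True test-stimulus x latent matrix.
#' @param subset Integer vector of dimension indices (>= 2 dimensions;
#'   default all).
#' @param subsetName Label recorded in the result.
#' @param method Correlation used for pair scoring (`"pearson"` default,
#'   `"spearman"` available).
#' @return A \linkS4class{DecodingResult}.
#' @export
pairwiseIdentityAccuracy <- function(xHat, xTrue, subset = NULL,
                                     subsetName = "all",
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assertMatrix(xHat); assertMatrix(xTrue)
  if (!all(dim(xHat) == dim(xTrue))) stop("xHat and xTrue shapes differ")
  if (is.null(subset)) subset <- seq_len(ncol(xTrue))
  subset <- as.integer(subset)
  if (length(subset) < 2L) stop("subset must contain at least 2 dimensions")
  if (any(subset < 1L | subset > ncol(xTrue))) stop("invalid dimension indices in subset")
  n <- nrow(xTrue)
  A <- xHat[, subset, drop = FALSE]
  B <- xTrue[, subset, drop = FALSE]
  if (method == "spearman") {
    A <- t(apply(A, 1, rank))
    B <- t(apply(B, 1, rank))
  }
  constA <- apply(A, 1, sd) == 0
  constB <- apply(B, 1, sd) == 0
  # row-by-row correlation matrix: C[i, j] = cor(A[i, ], B[j, ])
  As <- t(scale(t(A)))
  Bs <- t(scale(t(B)))
  C <- tcrossprod(As, Bs) / (length(subset) - 1)

  target <- rep(seq_len(n), each = n - 1L)
  foil <- unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i)))
  usable <- !(constA[target] | constB[target] | constB[foil])
  if (any(!usable)) {
    warning(sum(!usable), " pair(s) skipped: constant subset vector")
  }
  target <- target[usable]; foil <- foil[usable]
  same <- C[cbind(target, target)]
  other <- C[cbind(target, foil)]
  score <- ifelse(same > other, 1, ifelse(same == other, 0.5, 0))
  new("DecodingResult",
      accuracy = if (length(score)) sum(score) / length(score) else 0,
      nComparisons = length(score),
      subsetName = subsetName,
      perPair = data.frame(target = target, foil = foil, score = score))
}

#' Identity decoding over a battery of dimension subsets
#'
#' Runs [pairwiseIdentityAccuracy()] once per named subset (for example
#' identity-relevant, identity-irrelevant, entangled, relevant + entangled,
#' all). Decoding is done once with the full weight matrix; subsets act on
#' the decoded latents. Set `restrictedPinv = TRUE` to instead re-derive the
#' pseudo-inverse from the subset's rows of W (alternative mode, labelled in
#' the result names).
#'
#' @param xHat Decoded test-stimulus x latent matrix (ignored when
#'   `restrictedPinv` with `fit`/`y` supplied).
#' @param xTrue True test-stimulus x latent matrix.
#' @param subsets Named list of integer index vectors.
#' @param method Pair-scoring correlation, see [pairwiseIdentityAccuracy()].
#' @param restrictedPinv Logical; re-decode per subset with a
#'   subset-restricted pseudo-inverse.
#' @param fit,y Required when `restrictedPinv = TRUE`: the encoding fit and
#'   the test responses.
#' @return Named list of \linkS4class{DecodingResult} objects.
#' @export
subsetBattery <- function(xHat, xTrue, subsets, method = c("pearson", "spearman"),
                          restrictedPinv = FALSE, fit = NULL, y = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(subsets), length(subsets) >= 1L)
  if (is.null(names(subsets))) names(subsets) <- paste0("subset", seq_along(subsets))
  if (any(lengths(subsets) == 0L)) stop("empty subset")
  out <- lapply(names(subsets), function(nm) {
    s <- subsets[[nm]]
    if (restrictedPinv) {
      if (is.null(fit) || is.null(y)) stop("restrictedPinv requires fit and y")
      Wsub <- encodingWeights(fit)[s, , drop = FALSE]
      xh <- (y - matrix(faceBias(fit), nrow(y), ncol(y), byrow = TRUE)) %*% MASS::ginv(Wsub)
      pairwiseIdentityAccuracy(xh, xTrue[, s, drop = FALSE],
                               subsetName = paste0(nm, " (restricted pinv)"),
                               method = method)
    } else {
      pairwiseIdentityAccuracy(xHat, xTrue, subset = s, subsetName = nm,
                               method = method)
    }
  })
  names(out) <- names(subsets)
  out
}
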