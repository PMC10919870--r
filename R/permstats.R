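# Permutation-based inference for encoding performance. All p-values use the
# add-one convention p = (1 + #{null >= observed}) / (1 + resamples) so that
# p is never 0.

.permP <- function(observed, nulls, tail) {
  if (tail == "one") {
    (1 + sum(nulls >= observed)) / (1 + length(nulls))
  } else {
    (1 + sum(abs(nulls) >= abs(observed))) / (1 + length(nulls))
  }
}

# Centered column-rank matrix with per-column sums of squares, the
# building block of the fast Spearman statistics below. Constant columns get
# r = 0, matching spearmanColumns().
.centeredRanks <- function(m) {
  r <- apply(m, 2, rank)
  if (is.null(dim(r))) r <- matrix(r, ncol = ncol(m))
  r <- r - (nrow(m) + 1) / 2
  attr(r, "ss") <- colSums(r^2)
  r
}

.meanSpearmanRanked <- function(rp, ro, perm = NULL) {
  den <- sqrt(attr(rp, "ss") * attr(ro, "ss"))
  if (!is.null(perm)) ro <- ro[perm, , drop = FALSE]
  num <- colSums(rp * ro)
  mean(ifelse(den > 0, num / den, 0))
}

.meanSpearman <- function(predicted, observed, voxels = NULL) {
  if (!is.null(voxels)) {
    predicted <- predicted[, voxels, drop = FALSE]
    observed <- observed[, voxels, drop = FALSE]
  }
  .meanSpearmanRanked(.centeredRanks(predicted), .centeredRanks(observed))
}

#' Permutation test of above-chance encoding performance
#'
#' The observed statistic is the mean Spearman correlation (over the ROI's
#' voxels) between predicted and observed test responses. Each resample
#' permutes the test-image labels of the observed data and recomputes the
#' statistic; the one-tailed p-value uses the add-one convention.
#'
#' @param predicted,observed Test-stimulus x voxel matrices.
#' @param voxels Optional voxel indices restricting the ROI.
#' @param resamples Number of label permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return A \linkS4class{PermutationResult}.
#' @export
permTestAboveChance <- function(predicted, observed, voxels = NULL,
                                resamples = 1000L, seed = 1L) {
  stopifnot(resamples >= 100L)
  assertMatrix(predicted); assertMatrix(observed)
  if (!is.null(voxels)) {
    predicted <- predicted[, voxels, drop = FALSE]
    observed <- observed[, voxels, drop = FALSE]
  }
  # ranks are invariant under label permutation, so rank once and permute rows
  rp <- .centeredRanks(predicted)
  ro <- .centeredRanks(observed)
  obs <- .meanSpearmanRanked(rp, ro)
  n <- nrow(observed)
  withSeed(seed, {
    nulls <- vapply(seq_len(resamples), function(i) {
      .meanSpearmanRanked(rp, ro, perm = sample(n))
    }, numeric(1))
    new("PermutationResult", observed = obs, nullSamples = nulls,
        pValue = .permP(obs, nulls, "one"), tail = "one",
        level = "individual", seed = as.integer(seed))
  })
}

#' Permutation test of an encoding-performance difference between models
#'
#' Statistic: mean r(model A) - mean r(model B) against the same observed
#' responses. The null swaps the two models' predictions independently per
#' test image ("shuffled model labels"), preserving the voxelwise correlation
#' structure; the p-value is two-tailed.
#'
#' @param predsA,predsB Test-stimulus x voxel predictions of the two models.
#' @param observed Test-stimulus x voxel observed responses.
#' @inheritParams permTestAboveChance
#' @return A \linkS4class{PermutationResult}.
#' @export
permTestModelDiff <- function(predsA, predsB, observed, voxels = NULL,
                              resamples = 1000L, seed = 1L) {
  stopifnot(resamples >= 100L)
  assertMatrix(predsA); assertMatrix(predsB); assertMatrix(observed)
  if (!all(dim(predsA) == dim(predsB)) || !all(dim(predsA) == dim(observed))) {
    stop("prediction and observation shapes must match")
  }
  obs <- .meanSpearman(predsA, observed, voxels) - .meanSpearman(predsB, observed, voxels)
  n <- nrow(observed)
  withSeed(seed, {
    nulls <- vapply(seq_len(resamples), function(i) {
      swap <- runif(n) < 0.5
      a <- predsA; bm <- predsB
      a[swap, ] <- predsB[swap, , drop = FALSE]
      bm[swap, ] <- predsA[swap, , drop = FALSE]
      .meanSpearman(a, observed, voxels) - .meanSpearman(bm, observed, voxels)
    }, numeric(1))
    new("PermutationResult", observed = obs, nullSamples = nulls,
        pValue = .permP(obs, nulls, "two"), tail = "two",
        level = "individual", seed = as.integer(seed))
  })
}

#' Permutation test of a predictivity difference between two ROIs
#'
#' Statistic: mean per-voxel statistic in ROI 1 minus ROI 2. The null
#' shuffles the ROI assignment of the voxels; the p-value is two-tailed.
#'
#' @param stat1,stat2 Per-voxel statistics (e.g. single-dimension prediction
#'   correlations) for the two ROIs.
#' @inheritParams permTestAboveChance
#' @return A \linkS4class{PermutationResult}.
#' @export
permTestRoiDiff <- function(stat1, stat2, resamples = 1000L, seed = 1L) {
  stopifnot(resamples >= 100L)
  obs <- mean(stat1) - mean(stat2)
  pool <- c(stat1, stat2)
  n1 <- length(stat1)
  withSeed(seed, {
    nulls <- vapply(seq_len(resamples), function(i) {
      idx <- sample(length(pool), n1)
      mean(pool[idx]) - mean(pool[-idx])
    }, numeric(1))
    new("PermutationResult", observed = obs, nullSamples = nulls,
        pValue = .permP(obs, nulls, "two"), tail = "two",
        level = "individual", seed = as.integer(seed))
  })
}

#' Group-level permutation result from subject-level results
#'
#' The group statistic is the mean of the subjects' observed statistics; the
#' i-th group null sample is the mean over subjects of each subject's i-th
#' null sample. The tail is inherited (and must agree across subjects).
#'
#' @param results List of \linkS4class{PermutationResult} objects, one per
#'   subject, with equal resample counts.
#' @return A \linkS4class{PermutationResult} at group level.
#' @export
groupLevel <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  if (length(results) == 1L) {
    warning("single subject: group-level result equals the individual result")
  }
  tails <- vapply(results, function(r) r@tail, character(1))
  if (length(unique(tails)) != 1L) stop("subjects use different tails")
  lens <- vapply(results, function(r) length(nullSamples(r)), integer(1))
  if (length(unique(lens)) != 1L) stop("mismatched resample counts across subjects")
  obs <- mean(vapply(results, observedStat, numeric(1)))
  nulls <- rowMeans(vapply(results, nullSamples, numeric(lens[1])))
  new("PermutationResult", observed = obs, nullSamples = nulls,
      pValue = .permP(obs, nulls, tails[1]), tail = tails[1],
      level = "group", seed = results[[1]]@seed)
}

#' Benjamini-Hochberg adjustment across a set of permutation results
#'
#' Optional multiple-comparison correction (off by default in the pipeline,
#' matching the single-test reporting convention).
#'
#' @param results List of \linkS4class{PermutationResult} objects.
#' @return Numeric vector of BH-adjusted p-values.
#' @export
adjustPValues <- function(results) {
  stats::p.adjust(vapply(results, pValue, numeric(1)), method = "BH")
}
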