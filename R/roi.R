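# Voxel selection by the combined selectivity + reliability metric
# v = v_s + v_r, z-scored within parcel (population sd). z-scoring makes the
# selection invariant to affine rescaling of either raw score.

#' Select the top fraction of voxels per parcel
#'
#' Z-scores the selectivity statistic and the split-half reliability within
#' each parcel (population sd), sums them into the selection metric
#' v = v_s + v_r, and flags the top `ceiling(fraction * n)` voxels of each
#' parcel by v. Ties are broken deterministically by voxel index. When raw
#' p-values are supplied instead of a selectivity statistic, transform them
#' with `-log10(p)` first so that larger still means more selective.
#'
#' @param stats A \linkS4class{LocalizerStats}, or a numeric vector of
#'   per-voxel selectivity statistics.
#' @param reliability Numeric vector of per-voxel reliabilities.
#' @param parcel Character/integer parcel id per voxel; defaults to the
#'   parcel labels in `stats` or a single parcel.
#' @param fraction Fraction of voxels to keep per parcel, in (0, 1].
#' @return A \linkS4class{VoxelSelection}.
#' @examples
#' sel <- parcelSelect(rnorm(100), rnorm(100), fraction = 0.1)
#' sum(isSelected(sel))
#' @export
parcelSelect <- function(stats, reliability, parcel = NULL, fraction = 0.1) {
  if (is(stats, "LocalizerStats")) {
    if (is.null(parcel)) parcel <- parcels(stats)
    stats <- selectivity(stats)
  }
  n <- length(stats)
  stopifnot(length(reliability) == n, fraction > 0, fraction <= 1)
  if (is.null(parcel)) parcel <- rep("all", n)
  parcel <- as.character(parcel)
  parcel[is.na(parcel)] <- "unparcellated"
  vS <- numeric(n); vR <- numeric(n); selected <- logical(n)
  for (p in unique(parcel)) {
    idx <- which(parcel == p)
    if (length(idx) < 2L) stop("each parcel needs at least 2 voxels")
    vS[idx] <- zscorePop(stats[idx])
    vR[idx] <- zscorePop(reliability[idx])
    v <- vS[idx] + vR[idx]
    keep <- ceiling(fraction * length(idx))
    ord <- order(-v, idx)   # deterministic tie-break by voxel index
    selected[idx[ord[seq_len(keep)]]] <- TRUE
  }
  new("VoxelSelection", vS = vS, vR = vR, v = vS + vR,
      selected = selected, parcel = parcel)
}

#' Whole-brain voxel selection by a threshold in sd units
#'
#' Flags voxels whose metric exceeds the mean by `kSd` standard deviations
#' (population sd).
#'
#' @param v Numeric per-voxel metric (typically v_s + v_r).
#' @param kSd Threshold in sd units (default 1.5).
#' @return Logical vector of selection flags.
#' @examples
#' mean(wholeBrainSelect(rnorm(1e4)))  # about the 1.5-sd upper tail
#' @export
wholeBrainSelect <- function(v, kSd = 1.5) {
  stopifnot(length(v) >= 2L)
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) return(rep(FALSE, length(v)))
  v > mean(v) + kSd * s
}
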