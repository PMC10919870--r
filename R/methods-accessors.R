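# Accessor and show methods.

#' @rdname accessors
setMethod("encodingWeights", "GroundTruthEncoding", function(object) object@W)
#' @rdname accessors
setMethod("encodingWeights", "EncodingFit", function(object) object@W)
#' @rdname accessors
setMethod("faceBias", "GroundTruthEncoding", function(object) object@b)
#' @rdname accessors
setMethod("faceBias", "EncodingFit", function(object) object@b)
#' @rdname accessors
setMethod("noiseSd", "GroundTruthEncoding", function(object) object@noiseSd)
#' @rdname accessors
setMethod("sparsityPlan", "GroundTruthEncoding", function(object) object@sparsityPlan)

#' @rdname accessors
setMethod("factorSpec", "SyntheticFaceSet", function(object) object@spec)
#' @rdname accessors
setMethod("trainFactors", "SyntheticFaceSet", function(object) object@trainFactors)
#' @rdname accessors
setMethod("testFactors", "SyntheticFaceSet", function(object) object@testFactors)
#' @rdname accessors
setMethod("trainImages", "SyntheticFaceSet", function(object) object@trainImages)
#' @rdname accessors
setMethod("testImages", "SyntheticFaceSet", function(object) object@testImages)

#' @rdname accessors
setMethod("trainResponses", "FaceVoxelExperiment", function(object) {
  sel <- SummarizedExperiment::colData(object)$set == "train"
  t(SummarizedExperiment::assay(object, "response")[, sel, drop = FALSE])
})
#' @rdname accessors
setMethod("testResponses", "FaceVoxelExperiment", function(object) {
  sel <- SummarizedExperiment::colData(object)$set == "test"
  t(SummarizedExperiment::assay(object, "response")[, sel, drop = FALSE])
})
#' @rdname accessors
setMethod("testRepeatArray", "FaceVoxelExperiment", function(object) object@testRepeats)

#' @rdname accessors
setMethod("designValues", "DesignMatrix", function(object) object@values)
#' @rdname accessors
setMethod("columnRoles", "DesignMatrix", function(object) object@columnRoles)
#' @rdname accessors
setMethod("designMode", "DesignMatrix", function(object) object@mode)

#' @rdname accessors
setMethod("predictedResponses", "PredictionResult", function(object) object@predicted)
#' @rdname accessors
setMethod("perVoxelR", "PredictionResult", function(object) object@perVoxelR)
#' @rdname accessors
setMethod("roiMeans", "PredictionResult", function(object) object@roiMeans)

#' @rdname accessors
setMethod("selectionMetric", "VoxelSelection", function(object) object@v)
#' @rdname accessors
setMethod("isSelected", "VoxelSelection", function(object) object@selected)
#' @rdname accessors
setMethod("parcels", "VoxelSelection", function(object) object@parcel)

#' @rdname accessors
setMethod("perDimR", "PreferenceMap", function(object) object@perDimR)
#' @rdname accessors
setMethod("winners", "PreferenceMap", function(object) object@winner)
#' @rdname accessors
setMethod("roiProfiles", "PreferenceMap", function(object) object@roiProfiles)

#' @rdname accessors
setMethod("accuracy", "DecodingResult", function(object) object@accuracy)
#' @rdname accessors
setMethod("nComparisons", "DecodingResult", function(object) object@nComparisons)

#' @rdname accessors
setMethod("pValue", "PermutationResult", function(object) object@pValue)
#' @rdname accessors
setMethod("nullSamples", "PermutationResult", function(object) object@nullSamples)
#' @rdname accessors
setMethod("observedStat", "PermutationResult", function(object) object@observed)

#' @rdname accessors
setMethod("trainingLog", "VaeModel", function(object) object@trainingLog)
#' @rdname accessors
setMethod("modelConfig", "VaeModel", function(object) object@config)

#' @rdname accessors
setMethod("selectivity", "LocalizerStats", function(object) object@selectivityStat)
#' @rdname accessors
setMethod("parcels", "LocalizerStats", function(object) object@parcelLabels)

setMethod("show", "GroundTruthEncoding", function(object) {
  cat("GroundTruthEncoding:", nrow(object@W), "latent dims x", ncol(object@W), "voxels\n")
  nSingle <- sum(lengths(object@sparsityPlan) == 1L)
  cat("  single-dimension voxels:", nSingle, "| runs:", nrow(object@driftCoefs),
      "| noise sd range:", paste(signif(range(object@noiseSd), 3), collapse = " - "), "\n")
})

setMethod("show", "SyntheticFaceSet", function(object) {
  cat("SyntheticFaceSet:", nrow(object@trainFactors), "training faces,",
      nrow(object@testFactors), "test faces,", dim(object@trainImages)[2],
      "px, seed", object@seed, "\n")
  cat("  factors:", paste(object@spec$name, collapse = ", "), "\n")
})

setMethod("show", "SimulatedSession", function(object) {
  cat("SimulatedSession:", nrow(object@series), "time points x", ncol(object@series),
      "voxels, TR =", object@TR, "s,", length(unique(object@runIndex)), "run(s),",
      nrow(object@events), "events\n")
})

setMethod("show", "EncodingFit", function(object) {
  cat("EncodingFit (", object@mode, " mode): ", nrow(object@W), " latent dims x ",
      ncol(object@W), " voxels, ", nrow(object@nuisance), " nuisance coefficients\n",
      sep = "")
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult:", ncol(object@predicted), "voxels, mean Spearman r =",
      signif(mean(object@perVoxelR), 3), "\n")
  if (length(object@roiMeans)) {
    cat("  ROI means:", paste(sprintf("%s=%.3f", names(object@roiMeans), object@roiMeans),
                              collapse = ", "), "\n")
  }
})

setMethod("show", "VoxelSelection", function(object) {
  cat("VoxelSelection:", sum(object@selected), "of", length(object@selected),
      "voxels selected across", length(unique(object@parcel)), "parcel(s)\n")
})

setMethod("show", "PreferenceMap", function(object) {
  cat("PreferenceMap:", nrow(object@perDimR), "voxels x", ncol(object@perDimR), "dimensions;",
      sum(is.na(object@winner)), "voxel(s) with no positive winner\n")
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult [%s]: accuracy %.3f over %d comparisons\n",
              object@subsetName, object@accuracy, object@nComparisons))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult (%s-tailed, %s level): observed %.4f, p = %.4g (%d resamples)\n",
              object@tail, object@level, object@observed, object@pValue,
              length(object@nullSamples)))
})

setMethod("show", "VaeModel", function(object) {
  cfg <- object@config
  cat(sprintf("VaeModel: %s, latentDim %d, beta %g, gamma %g, %d epochs (seed %d)\n",
              cfg$family, cfg$latentDim, cfg$beta, cfg$gamma, cfg$epochs, cfg$seed))
  if (nrow(object@trainingLog)) {
    cat(sprintf("  final held-out reconstruction: %.4f (epoch 1: %.4f)\n",
                tail(object@trainingLog$heldoutReconstruction, 1),
                object@trainingLog$heldoutReconstruction[1]))
  }
})

setMethod("show", "LocalizerStats", function(object) {
  cat("LocalizerStats:", length(object@selectivityStat), "voxels,",
      length(unique(object@parcelLabels[!is.na(object@parcelLabels)])), "parcel(s)\n")
})
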