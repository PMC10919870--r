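# Generics and accessors. Slots are never reached into directly by user code;
# these accessors are the supported surface.

#' @name accessors
#' @title Accessors for LatentFaces containers
#' @description Small accessor generics for the S4 containers. Each returns
#'   the corresponding component without exposing slot layout.
#' @param object An object of the documented class.
#' @param x An object of the documented class.
#' @param ... Unused.
NULL

#' @rdname accessors
#' @export
setGeneric("encodingWeights", function(object) standardGeneric("encodingWeights"))
#' @rdname accessors
#' @export
setGeneric("faceBias", function(object) standardGeneric("faceBias"))
#' @rdname accessors
#' @export
setGeneric("noiseSd", function(object) standardGeneric("noiseSd"))
#' @rdname accessors
#' @export
setGeneric("sparsityPlan", function(object) standardGeneric("sparsityPlan"))
#' @rdname accessors
#' @export
setGeneric("factorSpec", function(object) standardGeneric("factorSpec"))
#' @rdname accessors
#' @export
setGeneric("trainFactors", function(object) standardGeneric("trainFactors"))
#' @rdname accessors
#' @export
setGeneric("testFactors", function(object) standardGeneric("testFactors"))
#' @rdname accessors
#' @export
setGeneric("trainImages", function(object) standardGeneric("trainImages"))
#' @rdname accessors
#' @export
setGeneric("testImages", function(object) standardGeneric("testImages"))
#' @rdname accessors
#' @export
setGeneric("trainResponses", function(object) standardGeneric("trainResponses"))
#' @rdname accessors
#' @export
setGeneric("testResponses", function(object) standardGeneric("testResponses"))
#' @rdname accessors
#' @export
setGeneric("testRepeatArray", function(object) standardGeneric("testRepeatArray"))
#' @rdname accessors
#' @export
setGeneric("designValues", function(object) standardGeneric("designValues"))
#' @rdname accessors
#' @export
setGeneric("columnRoles", function(object) standardGeneric("columnRoles"))
#' @rdname accessors
#' @export
setGeneric("designMode", function(object) standardGeneric("designMode"))
#' @rdname accessors
#' @export
setGeneric("predictedResponses", function(object) standardGeneric("predictedResponses"))
#' @rdname accessors
#' @export
setGeneric("perVoxelR", function(object) standardGeneric("perVoxelR"))
#' @rdname accessors
#' @export
setGeneric("roiMeans", function(object) standardGeneric("roiMeans"))
#' @rdname accessors
#' @export
setGeneric("selectionMetric", function(object) standardGeneric("selectionMetric"))
#' @rdname accessors
#' @export
setGeneric("isSelected", function(object) standardGeneric("isSelected"))
#' @rdname accessors
#' @export
setGeneric("perDimR", function(object) standardGeneric("perDimR"))
#' @rdname accessors
#' @export
setGeneric("winners", function(object) standardGeneric("winners"))
#' @rdname accessors
#' @export
setGeneric("roiProfiles", function(object) standardGeneric("roiProfiles"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("nComparisons", function(object) standardGeneric("nComparisons"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("nullSamples", function(object) standardGeneric("nullSamples"))
#' @rdname accessors
#' @export
setGeneric("observedStat", function(object) standardGeneric("observedStat"))
#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("selectivity", function(object) standardGeneric("selectivity"))
#' @rdname accessors
#' @export
setGeneric("parcels", function(object) standardGeneric("parcels"))
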