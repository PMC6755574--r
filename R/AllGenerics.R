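#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes, following the usual
#' accessor-over-slot convention.
#'
#' @param object an object of one of the chemperf classes.
#' @param ... passed to methods.
#' @return the slot value named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("responseType", function(object) standardGeneric("responseType"))

#' @rdname accessors
#' @export
setGeneric("responseValues", function(object) standardGeneric("responseValues"))

#' @rdname accessors
#' @export
setGeneric("observationIds", function(object) standardGeneric("observationIds"))

#' @rdname accessors
#' @export
setGeneric("descriptorSets", function(object) standardGeneric("descriptorSets"))

#' @rdname accessors
#' @export
setGeneric("descriptorSetNames", function(object) standardGeneric("descriptorSetNames"))

#' @rdname accessors
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))

#' @rdname accessors
#' @export
setGeneric("foldAssignments", function(object, ...) standardGeneric("foldAssignments"))

#' @rdname accessors
#' @export
setGeneric("cvSeeds", function(object) standardGeneric("cvSeeds"))

#' @rdname accessors
#' @export
setGeneric("predictionKeys", function(object) standardGeneric("predictionKeys"))

#' @rdname accessors
#' @export
setGeneric("performanceValues", function(object) standardGeneric("performanceValues"))

#' @rdname accessors
#' @export
setGeneric("measureName", function(object) standardGeneric("measureName"))

#' @rdname accessors
#' @export
setGeneric("measureOrientation", function(object) standardGeneric("measureOrientation"))

#' @rdname accessors
#' @export
setGeneric("pairwiseTable", function(object) standardGeneric("pairwiseTable"))

#' @rdname accessors
#' @export
setGeneric("comboOrdering", function(object) standardGeneric("comboOrdering"))

#' @rdname accessors
#' @export
setGeneric("comboMeans", function(object) standardGeneric("comboMeans"))

#' @rdname accessors
#' @export
setGeneric("t2Values", function(object) standardGeneric("t2Values"))

#' @rdname accessors
#' @export
setGeneric("upperControlLimit", function(object) standardGeneric("upperControlLimit"))

#' @rdname accessors
#' @export
setGeneric("outlierIndices", function(object) standardGeneric("outlierIndices"))

#' Extract out-of-fold predictions for one combination
#'
#' @param object a \linkS4class{PredictionStore}.
#' @param split split index.
#' @param set descriptor-set name.
#' @param method method name.
#' @return numeric vector of n out-of-fold predicted scores.
#' @export
setGeneric("getPredictions",
  function(object, split, set, method) standardGeneric("getPredictions"))
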