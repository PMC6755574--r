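# Accessor and show methods for the S4 classes.

#' @rdname accessors
#' @export
setMethod("responseType", "ModelingDataset", function(object) object@responseType)

#' @rdname accessors
#' @export
setMethod("responseValues", "ModelingDataset", function(object) object@response)

#' @rdname accessors
#' @export
setMethod("observationIds", "ModelingDataset", function(object) object@ids)

#' @rdname accessors
#' @export
setMethod("descriptorSets", "ModelingDataset", function(object) object@descriptorSets)

#' @rdname accessors
#' @export
setMethod("descriptorSetNames", "ModelingDataset",
  function(object) names(object@descriptorSets))

#' @rdname accessors
#' @export
setMethod("nObs", "ModelingDataset", function(object) length(object@response))

#' Show method
#' @param object the object
#' @name show-methods
#' @keywords internal
#' @export
setMethod("show", "ModelingDataset", function(object) {
  widths <- vapply(object@descriptorSets, ncol, integer(1))
  cat("ModelingDataset:", nObs(object), "observations,",
      object@responseType, "response\n")
  if (object@responseType == "binary")
    cat("  positives:", sum(object@response == 1), "\n")
  cat("  descriptor sets:",
      paste(sprintf("%s (%d)", names(widths), widths), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("nObs", "CvPlan", function(object) object@nobs)

#' @rdname accessors
#' @export
setMethod("cvSeeds", "CvPlan", function(object) object@seeds)

#' @rdname accessors
#' @export
#' @param split split index (for \code{foldAssignments}).
setMethod("foldAssignments", "CvPlan", function(object, split = NULL) {
  if (is.null(split)) object@assignments else object@assignments[[split]]
})

#' Show method
#' @param object the object
#' @name show-methods
#' @keywords internal
#' @export
setMethod("show", "CvPlan", function(object) {
  cat("CvPlan:", length(object@seeds), "split(s) x", object@nfolds,
      "folds over", object@nobs, "observations\n")
  cat("  seeds:", paste(object@seeds, collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("predictionKeys", "PredictionStore", function(object) names(object@entries))

#' @rdname accessors
#' @export
setMethod("nObs", "PredictionStore", function(object) length(object@observed))

#' @rdname accessors
#' @export
setMethod("responseType", "PredictionStore", function(object) object@responseType)

#' @rdname accessors
#' @export
setMethod("responseValues", "PredictionStore", function(object) object@observed)

#' @rdname accessors
#' @export
setMethod("observationIds", "PredictionStore", function(object) object@ids)

storeKey <- function(split, set, method) paste(split, set, method, sep = "|")

#' @rdname getPredictions
#' @export
setMethod("getPredictions", "PredictionStore", function(object, split, set, method) {
  key <- storeKey(split, set, method)
  if (!key %in% names(object@entries))
    stop("no predictions stored for (split=", split, ", set=", set,
         ", method=", method, ")")
  object@entries[[key]]
})

#' Show method
#' @param object the object
#' @name show-methods
#' @keywords internal
#' @export
setMethod("show", "PredictionStore", function(object) {
  cat("PredictionStore:", length(object@entries), "combination(s) x",
      length(object@observed), "observations (", object@responseType,
      "response )\n")
  if (length(object@failures))
    cat("  skipped:", paste(names(object@failures), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("performanceValues", "PerformanceTable", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("measureName", "PerformanceTable", function(object) object@measure)

#' @rdname accessors
#' @export
setMethod("measureOrientation", "PerformanceTable", function(object) object@orientation)

#' Show method
#' @param object the object
#' @name show-methods
#' @keywords internal
#' @export
setMethod("show", "PerformanceTable", function(object) {
  cat("PerformanceTable:", nrow(object@values), "split(s) x",
      ncol(object@values), "D-M combination(s), measure:", object@measure,
      paste0("(", object@orientation, ")"), "\n")
})

#' Show method
#' @param object the object
#' @name show-methods
#' @keywords internal
#' @export
setMethod("show", "AnovaResult", function(object) {
  cat("Blocked two-way ANOVA (Y_ij = mu + alpha_i + beta_j + eps_ij)\n")
  tab <- data.frame(
    Df = object@df[c("split", "combo", "error")],
    `Sum Sq` = object@ss[c("split", "combo", "error")],
    `Mean Sq` = object@ms[c("split", "combo", "error")],
    `F value` = c(object@fstat["split"], object@fstat["combo"], NA),
    `Pr(>F)` = c(object@pvalue["split"], object@pvalue["combo"], NA),
    check.names = FALSE
  )
  rownames(tab) <- c("split", "D-M combination", "residual")
  print(tab)
})

#' @rdname accessors
#' @export
setMethod("pairwiseTable", "ComparisonResult", function(object) object@pairs)

#' @rdname accessors
#' @export
setMethod("comboOrdering", "ComparisonResult", function(object) object@ordering)

#' @rdname accessors
#' @export
setMethod("comboMeans", "ComparisonResult", function(object) object@means)

#' @rdname accessors
#' @export
setMethod("measureName", "ComparisonResult", function(object) object@measure)

#' @rdname accessors
#' @export
setMethod("measureOrientation", "ComparisonResult", function(object) object@orientation)

#' Show method
#' @param object the object
#' @name show-methods
#' @keywords internal
#' @export
setMethod("show", "ComparisonResult", function(object) {
  cat("Tukey-Kramer comparisons of", length(object@ordering),
      "D-M combinations (", nrow(object@pairs), "pairs ), measure:",
      object@measure, "\n")
  cat("  best -> worst:", paste(utils::head(object@ordering, 5), collapse = " > "),
      if (length(object@ordering) > 5) "..." else "", "\n")
  cat("  pairs with p <=", object@bands[1], ":",
      sum(object@pairs$p_adjusted <= object@bands[1]), "\n")
})

#' @rdname accessors
#' @export
setMethod("t2Values", "ControlChartResult", function(object) object@t2)

#' @rdname accessors
#' @export
setMethod("upperControlLimit", "ControlChartResult", function(object) object@ucl)

#' @rdname accessors
#' @export
setMethod("outlierIndices", "ControlChartResult", function(object) object@outliers)

#' Show method
#' @param object the object
#' @name show-methods
#' @keywords internal
#' @export
setMethod("show", "ControlChartResult", function(object) {
  cat("Hotelling T2 control chart:", length(object@t2), "external observation(s)\n")
  cat("  UCL =", format(object@ucl, digits = 4), "at alpha =", object@alpha,
      "->", length(object@outliers), "outside the applicability domain\n")
})
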