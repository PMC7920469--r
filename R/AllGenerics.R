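#' Selected variable indices
#'
#' @param x a [SelectionResult-class] or [AggregationResult-class].
#' @return integer vector of selected indices (1-based, sorted).
#' @export
setGeneric("selectedVariables", function(x) standardGeneric("selectedVariables"))

#' Signed-max knockoff statistic of an object
#'
#' @param x a [KnockoffStatistics-class].
#' @return numeric vector W.
#' @export
setGeneric("wStatistic", function(x) standardGeneric("wStatistic"))

#' Entry values of originals and knockoffs
#'
#' @param x a [KnockoffStatistics-class].
#' @return two-column matrix with columns \code{Z} and \code{Ztilde}.
#' @export
setGeneric("entryValues", function(x) standardGeneric("entryValues"))

#' Per-run target levels of a schedule
#'
#' @param x a [LevelSchedule-class] or [AggregationResult-class].
#' @return numeric vector of levels q_1 ... q_k.
#' @export
setGeneric("scheduleLevels", function(x) standardGeneric("scheduleLevels"))

#' Per-run selection results of an aggregation
#'
#' @param x an [AggregationResult-class].
#' @return list of [SelectionResult-class] objects.
#' @export
setGeneric("perRunResults", function(x) standardGeneric("perRunResults"))

#' Selection threshold
#'
#' @param x a [SelectionResult-class].
#' @return the data-dependent threshold (possibly \code{Inf}).
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname selectedVariables
#' @export
setMethod("selectedVariables", "SelectionResult", function(x) x@selected)

#' @rdname selectedVariables
#' @export
setMethod("selectedVariables", "AggregationResult", function(x) x@selected)

#' @rdname wStatistic
#' @export
setMethod("wStatistic", "KnockoffStatistics", function(x) x@W)

#' @rdname entryValues
#' @export
setMethod("entryValues", "KnockoffStatistics", function(x)
  cbind(Z = x@Z, Ztilde = x@Ztilde))

#' @rdname scheduleLevels
#' @export
setMethod("scheduleLevels", "LevelSchedule", function(x) x@levels)

#' @rdname scheduleLevels
#' @export
setMethod("scheduleLevels", "AggregationResult", function(x) x@schedule@levels)

#' @rdname perRunResults
#' @export
setMethod("perRunResults", "AggregationResult", function(x) x@perRun)

#' @rdname thresholdValue
#' @export
setMethod("thresholdValue", "SelectionResult", function(x) x@threshold)

setMethod("show", "KnockoffModel", function(object) {
  cat("KnockoffModel with", nrow(object@sigma), "variables\n")
  cat("  decorrelation a: min", format(min(object@a), digits = 4),
      "max", format(max(object@a), digits = 4), "\n")
})

setMethod("show", "KnockoffStatistics", function(object) {
  cat("KnockoffStatistics (", object@family, " path), p = ",
      length(object@W), "\n", sep = "")
  cat("  W > 0:", sum(object@W > 0), " W < 0:", sum(object@W < 0),
      " W = 0:", sum(object@W == 0), "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat(if (object@plus) "knockoff+" else "knockoff",
      "selection at q =", object@q, "\n")
  cat("  threshold:", format(object@threshold, digits = 4),
      " selected:", length(object@selected), "variable(s)\n")
})

setMethod("show", "LevelSchedule", function(object) {
  cat("LevelSchedule (", object@mode, "), q = ", object@q,
      ", k = ", object@k, "\n", sep = "")
  cat("  levels:", paste(format(object@levels, digits = 4), collapse = ", "),
      "\n")
})

setMethod("show", "AggregationResult", function(object) {
  cat("AggregationResult:", if (object@plus) "knockoff+" else "knockoff",
      "aggregated over", object@schedule@k, "run(s)\n")
  cat("  schedule:", object@schedule@mode, "at q =", object@schedule@q, "\n")
  perRun <- vapply(object@perRun, function(r) length(r@selected), integer(1))
  cat("  per-run selections:", paste(perRun, collapse = ", "), "\n")
  cat("  union:", length(object@selected), "variable(s)\n")
})
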