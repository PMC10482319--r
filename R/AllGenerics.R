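#' @name growthCUB-accessors
#' @title Accessors for growthCUB classes
#'
#' @description Accessor generics for [CodonWeightTable-class],
#' [GrowthExpressionSet-class] and [SyntheticTruth-class] objects. Slot access
#' via `@` is not part of the API.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot or derived vector.
NULL

#' @rdname growthCUB-accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("codonWeights", function(x) standardGeneric("codonWeights"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("weightProvenance", function(x) standardGeneric("weightProvenance"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("growthRates", function(x) standardGeneric("growthRates"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("alignmentScores", function(x) standardGeneric("alignmentScores"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("isAle", function(x) standardGeneric("isAle"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("isMutantOrKo", function(x) standardGeneric("isMutantOrKo"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("plantedSlopes", function(x) standardGeneric("plantedSlopes"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("plantedBaselines", function(x) standardGeneric("plantedBaselines"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("biasStrengths", function(x) standardGeneric("biasStrengths"))

#' @rdname growthCUB-accessors
#' @export
setGeneric("plantedTerms", function(x) standardGeneric("plantedTerms"))

#' @rdname growthCUB-accessors
setMethod("metricName", "CodonWeightTable", function(x) x@metricName)

#' @rdname growthCUB-accessors
setMethod("codonWeights", "CodonWeightTable", function(x) x@weights)

#' @rdname growthCUB-accessors
setMethod("weightProvenance", "CodonWeightTable", function(x) x@provenance)

#' @rdname growthCUB-accessors
setMethod("exprValues", "GrowthExpressionSet",
          function(x) assay(x, "exprs"))

#' @rdname growthCUB-accessors
setMethod("growthRates", "GrowthExpressionSet",
          function(x) stats::setNames(colData(x)$growth_rate, colnames(x)))

#' @rdname growthCUB-accessors
setMethod("conditionIds", "GrowthExpressionSet",
          function(x) stats::setNames(colData(x)$condition_id, colnames(x)))

#' @rdname growthCUB-accessors
setMethod("alignmentScores", "GrowthExpressionSet",
          function(x) stats::setNames(colData(x)$alignment_score, colnames(x)))

#' @rdname growthCUB-accessors
setMethod("isAle", "GrowthExpressionSet",
          function(x) stats::setNames(colData(x)$is_ale, colnames(x)))

#' @rdname growthCUB-accessors
setMethod("isMutantOrKo", "GrowthExpressionSet",
          function(x) stats::setNames(colData(x)$is_mutant_or_ko, colnames(x)))

#' @rdname growthCUB-accessors
setMethod("scaleTag", "GrowthExpressionSet",
          function(x) metadata(x)$scale_tag)

#' @rdname growthCUB-accessors
setMethod("plantedSlopes", "SyntheticTruth", function(x) x@slopes)

#' @rdname growthCUB-accessors
setMethod("plantedBaselines", "SyntheticTruth", function(x) x@baselines)

#' @rdname growthCUB-accessors
setMethod("biasStrengths", "SyntheticTruth", function(x) x@biasStrengths)

#' @rdname growthCUB-accessors
setMethod("plantedTerms", "SyntheticTruth", function(x) x@plantedTerms)

setMethod("show", "CodonWeightTable", function(object) {
  w <- object@weights
  cat("CodonWeightTable '", object@metricName, "' with ", length(w),
      " codon weights\n", sep = "")
  cat("  range: [", format(min(w), digits = 4), ", ",
      format(max(w), digits = 4), "]\n", sep = "")
  cat("  provenance: ", object@provenance, "\n", sep = "")
})

setMethod("show", "GrowthExpressionSet", function(object) {
  methods::callNextMethod()
  gr <- colData(object)$growth_rate
  ok <- is.finite(gr)
  cat("scale_tag: ", metadata(object)$scale_tag, "\n", sep = "")
  cat(length(unique(colData(object)$condition_id)), " condition(s); ",
      "growth rate range: ",
      if (any(ok)) paste0("[", format(min(gr[ok]), digits = 3), ", ",
                          format(max(gr[ok]), digits = 3), "] 1/h")
      else "none reported", "\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: ", length(object@slopes), " genes x ",
      length(object@growthRates), " conditions (seed ", object@seed, ")\n",
      sep = "")
  cat("  noise sd ", object@noiseSd, "; ",
      sum(object@slopes < 0), " negative-slope genes; ",
      length(object@plantedTerms), " planted term(s)\n", sep = "")
})
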