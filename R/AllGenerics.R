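#' @rdname conditionIds
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))

#' @rdname conditionFactors
#' @export
setGeneric("conditionFactors", function(x) standardGeneric("conditionFactors"))

#' @rdname timePoints
#' @export
setGeneric("timePoints", function(x, condition) standardGeneric("timePoints"))

#' @rdname replicateCounts
#' @export
setGeneric("replicateCounts", function(x, condition)
    standardGeneric("replicateCounts"))

#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname sampleInfo
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname profileValues
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname rankingTable
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname linkTable
#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))

#' @rdname cvPredictions
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' @rdname meanAccuracy
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname meanAuc
#' @export
setGeneric("meanAuc", function(x) standardGeneric("meanAuc"))
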