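#' @rdname AbundanceTable
#' @param x an object.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname AbundanceTable
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))

#' @rdname AbundanceTable
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AbundanceTable
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname AbundanceTable
#' @export
setGeneric("taxRank", function(x) standardGeneric("taxRank"))

#' @rdname MutationMatrix
#' @param x an object.
#' @export
setGeneric("mutationCalls", function(x) standardGeneric("mutationCalls"))

#' @rdname MutationMatrix
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname MutationMatrix
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname MutationMatrix
#' @export
setGeneric("effectScope", function(x) standardGeneric("effectScope"))

#' @rdname RiskModel
#' @param x an object.
#' @export
setGeneric("positiveTaxa", function(x) standardGeneric("positiveTaxa"))

#' @rdname RiskModel
#' @export
setGeneric("negativeTaxa", function(x) standardGeneric("negativeTaxa"))

#' @rdname RiskModel
#' @export
setGeneric("targetClass", function(x) standardGeneric("targetClass"))

#' @rdname RiskIndexResult
#' @param x an object.
#' @export
setGeneric("riskIndices", function(x) standardGeneric("riskIndices"))

#' @rdname RiskIndexResult
#' @export
setGeneric("observedDiff", function(x) standardGeneric("observedDiff"))

#' @rdname RiskIndexResult
#' @export
setGeneric("mwuP", function(x) standardGeneric("mwuP"))

#' @rdname RiskIndexResult
#' @export
setGeneric("permP", function(x) standardGeneric("permP"))

#' @rdname CorrelationNetwork
#' @param x an object.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CorrelationNetwork
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
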