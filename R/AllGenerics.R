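#' @rdname genotypeCalls
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname variantKeys
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname caseStatus
#' @export
setGeneric("caseStatus", function(x) standardGeneric("caseStatus"))

#' @rdname caseStatus
#' @export
setGeneric("caseStatus<-", function(x, value) standardGeneric("caseStatus<-"))

#' @rdname caseStatus
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname caseStatus
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname PairTable-accessors
#' @export
setGeneric("pairCounts", function(x, ...) standardGeneric("pairCounts"))

#' @rdname PairTable-accessors
#' @export
setGeneric("nComplete", function(x) standardGeneric("nComplete"))

#' @rdname RiskModel-accessors
#' @export
setGeneric("riskLabels", function(x) standardGeneric("riskLabels"))

#' @rdname RiskModel-accessors
#' @export
setGeneric("riskThreshold", function(x) standardGeneric("riskThreshold"))

#' @rdname makeCvPlan
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' @rdname PenetranceModel
#' @export
setGeneric("penetranceTable", function(x) standardGeneric("penetranceTable"))
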