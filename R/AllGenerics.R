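#' @include hairpinBS-package.R
NULL

#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
#' @export
setGeneric("tReads", function(x) standardGeneric("tReads"))
#' @export
setGeneric("aReads", function(x) standardGeneric("aReads"))
#' @export
setGeneric("truthInfo", function(x) standardGeneric("truthInfo"))
#' @export
setGeneric("recoveredSeqs", function(x) standardGeneric("recoveredSeqs"))
#' @export
setGeneric("errorPositions", function(x) standardGeneric("errorPositions"))
#' @export
setGeneric("methCalls", function(x) standardGeneric("methCalls"))
#' @export
setGeneric("methStates", function(x) standardGeneric("methStates"))
#' @export
setGeneric("readInfo", function(x) standardGeneric("readInfo"))
#' @export
setGeneric("bestLocations", function(x) standardGeneric("bestLocations"))
#' @export
setGeneric("mapCategories", function(x) standardGeneric("mapCategories"))
#' @export
setGeneric("categorySummary", function(x) standardGeneric("categorySummary"))
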