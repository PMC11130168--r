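#' @import methods
NULL

#' @export
setGeneric("exprsMatrix", function(x, ...) standardGeneric("exprsMatrix"))

#' @export
setGeneric("batchLabels", function(x, ...) standardGeneric("batchLabels"))

#' @export
setGeneric("trueSubtypes", function(x, ...) standardGeneric("trueSubtypes"))

#' @export
setGeneric("trueModules", function(x, ...) standardGeneric("trueModules"))

#' @export
setGeneric("pairKeys", function(x, ...) standardGeneric("pairKeys"))

#' @export
setGeneric("kSelected", function(x, ...) standardGeneric("kSelected"))

#' @export
setGeneric("deltaKTable", function(x, ...) standardGeneric("deltaKTable"))

#' @export
setGeneric("consensusMatrices", function(x, ...) standardGeneric("consensusMatrices"))

#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @export
setGeneric("similarityMatrix", function(x, ...) standardGeneric("similarityMatrix"))

#' @export
setGeneric("adjacencyMatrix", function(x, ...) standardGeneric("adjacencyMatrix"))

#' @export
setGeneric("connectivity", function(x, ...) standardGeneric("connectivity"))

#' @export
setGeneric("tomDiss", function(x, ...) standardGeneric("tomDiss"))

#' @export
setGeneric("softPower", function(x, ...) standardGeneric("softPower"))

#' @export
setGeneric("moduleList", function(x, ...) standardGeneric("moduleList"))

#' @export
setGeneric("moduleSizes", function(x, ...) standardGeneric("moduleSizes"))

#' @export
setGeneric("unassignedGenes", function(x, ...) standardGeneric("unassignedGenes"))

#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @export
setGeneric("scoreMatrix", function(x, ...) standardGeneric("scoreMatrix"))

#' @export
setGeneric("moduleCoverage", function(x, ...) standardGeneric("moduleCoverage"))

#' @export
setGeneric("modelClasses", function(x, ...) standardGeneric("modelClasses"))

#' @export
setGeneric("cvMetrics", function(x, ...) standardGeneric("cvMetrics"))

#' @export
setGeneric("moduleSet", function(x, ...) standardGeneric("moduleSet"))

#' @export
setGeneric("transitionCounts", function(x, ...) standardGeneric("transitionCounts"))
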