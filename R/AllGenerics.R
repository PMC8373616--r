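#' @include AllClasses.R
NULL

#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @export
setGeneric("nodeRoles", function(x) standardGeneric("nodeRoles"))

#' @export
setGeneric("nodeRoles<-", function(x, value) standardGeneric("nodeRoles<-"))

#' @export
setGeneric("nodeScales", function(x) standardGeneric("nodeScales"))

#' @export
setGeneric("nodeGroups", function(x) standardGeneric("nodeGroups"))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @export
setGeneric("internalStates", function(x) standardGeneric("internalStates"))

#' @export
setGeneric("sensoryStates", function(x) standardGeneric("sensoryStates"))

#' @export
setGeneric("activeStates", function(x) standardGeneric("activeStates"))

#' @export
setGeneric("externalStates", function(x) standardGeneric("externalStates"))

#' @export
setGeneric("blanketStates", function(x) standardGeneric("blanketStates"))

#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @export
setGeneric("inputLabels", function(x) standardGeneric("inputLabels"))

#' @export
setGeneric("modelGraph", function(x) standardGeneric("modelGraph"))

#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @export
setGeneric("noiseAmplitudes", function(x) standardGeneric("noiseAmplitudes"))

#' @export
setGeneric("trajectoryStates", function(x) standardGeneric("trajectoryStates"))

#' @export
setGeneric("trajectoryTimes", function(x) standardGeneric("trajectoryTimes"))

#' @export
setGeneric("groupMapping", function(x) standardGeneric("groupMapping"))

#' @export
setGeneric("scaleIncrement", function(x) standardGeneric("scaleIncrement"))

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
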