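# Accessor generics for the package's S4 containers.

#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @export
setGeneric("degrees", function(object) standardGeneric("degrees"))

#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @export
setGeneric("enhancerRegions", function(object) standardGeneric("enhancerRegions"))

#' @export
setGeneric("cutoffSignal", function(object) standardGeneric("cutoffSignal"))

#' @export
setGeneric("isSuper", function(object) standardGeneric("isSuper"))

#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))

#' @export
setGeneric("combinationIndexValue",
           function(object) standardGeneric("combinationIndexValue"))

#' @export
setGeneric("pathwaySets", function(object) standardGeneric("pathwaySets"))

#' @export
setGeneric("oncogenicFlags", function(object) standardGeneric("oncogenicFlags"))

#' @export
setGeneric("profileMatrix", function(object) standardGeneric("profileMatrix"))

#' @export
setGeneric("skippedGenes", function(object) standardGeneric("skippedGenes"))

#' @export
setGeneric("geneAnnotation", function(object) standardGeneric("geneAnnotation"))
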