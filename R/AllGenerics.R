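#' @rdname GeneTable-class
#' @param object,x A package object.
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))

#' @rdname GeneTable-class
#' @export
setGeneric("geneData", function(x) standardGeneric("geneData"))

#' @rdname GeneTable-class
#' @export
setGeneric("contigNames", function(x) standardGeneric("contigNames"))

#' @rdname GeneTable-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterData", function(x) standardGeneric("clusterData"))

#' @rdname ClusterSet-class
#' @export
setGeneric("tiers", function(x) standardGeneric("tiers"))

#' @rdname ClusterSet-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusterSet-class
#' @export
setGeneric("detectionParams", function(x) standardGeneric("detectionParams"))

#' @rdname SubstrateMap-class
#' @export
setGeneric("substratesFor", function(x, family) standardGeneric("substratesFor"))

#' @rdname SubstrateMap-class
#' @export
setGeneric("mappedFamilies", function(x) standardGeneric("mappedFamilies"))
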