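#' @rdname MetaboSet
#' @param x,object a package object.
#' @export
setGeneric("metaboliteNames", function(x) standardGeneric("metaboliteNames"))

#' @rdname MetaboSet
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @rdname MetaboSet
#' @export
setGeneric("hmdbId", function(x) standardGeneric("hmdbId"))

#' @rdname MetaboSet
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname MetaboSet
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname MetaboSet
#' @export
setGeneric("validMetabolites", function(x) standardGeneric("validMetabolites"))

#' @rdname StructuralClustering
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname StructuralClustering
#' @export
setGeneric("numClusters", function(x) standardGeneric("numClusters"))

#' @rdname StructuralClustering
#' @export
setGeneric("silhouetteProfile", function(x) standardGeneric("silhouetteProfile"))

#' @rdname StructuralClustering
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))

#' @rdname ModuleSet
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @rdname ModuleSet
#' @export
setGeneric("moduleTree", function(x) standardGeneric("moduleTree"))

#' @rdname EigenMetabolites
#' @export
setGeneric("eigenScores", function(x) standardGeneric("eigenScores"))

#' @rdname EigenMetabolites
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname EigenMetabolites
#' @export
setGeneric("memberCorrelations", function(x) standardGeneric("memberCorrelations"))
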