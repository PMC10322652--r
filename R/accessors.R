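#' @describeIn MetaboSet metabolite names, in panel order.
#' @export
setMethod("metaboliteNames", "MetaboSet", function(x) rownames(x))

#' @describeIn MetaboSet named character vector of SMILES.
#' @export
setMethod("smiles", "MetaboSet", function(x) {
    stats::setNames(SummarizedExperiment::rowData(x)$smiles, rownames(x))
})

#' @describeIn MetaboSet named character vector of HMDB accessions ("" when
#'   absent).
#' @export
setMethod("hmdbId", "MetaboSet", function(x) {
    stats::setNames(SummarizedExperiment::rowData(x)$hmdb_id, rownames(x))
})

#' @describeIn MetaboSet per-sample group factor.
#' @export
setMethod("sampleGroups", "MetaboSet", function(x) {
    SummarizedExperiment::colData(x)$group
})

#' @describeIn MetaboSet concentration matrix, metabolites x samples.
#' @export
setMethod("concentrations", "MetaboSet", function(x) {
    SummarizedExperiment::assay(x, "concentration")
})

#' @describeIn MetaboSet names of metabolites whose SMILES parsed.
#' @export
setMethod("validMetabolites", "MetaboSet", function(x) {
    rownames(x)[SummarizedExperiment::rowData(x)$valid]
})

setMethod("show", "MetaboSet", function(object) {
    cat("MetaboSet:", nrow(object), "metabolites x", ncol(object), "samples\n")
    rd <- SummarizedExperiment::rowData(object)
    cat("  valid SMILES:", sum(rd$valid), "| with HMDB id:",
        sum(nzchar(rd$hmdb_id)), "\n")
    cat("  groups:", paste(levels(sampleGroups(object)), collapse = ", "), "\n")
})

#' @describeIn StructuralClustering named integer consensus labels.
#' @export
setMethod("clusterLabels", "StructuralClustering", function(x) x@labels)

#' @describeIn StructuralClustering the selected number of clusters.
#' @export
setMethod("numClusters", "StructuralClustering", function(x) x@k)

#' @describeIn StructuralClustering data.frame of repeat-averaged silhouettes
#'   (columns `k`, `mean`, `sd`).
#' @export
setMethod("silhouetteProfile", "StructuralClustering", function(x) x@silhouette)

#' @describeIn StructuralClustering representative 2-D embedding coordinates.
#' @export
setMethod("embedding", "StructuralClustering", function(x) x@embedding)

setMethod("show", "StructuralClustering", function(object) {
    cat("StructuralClustering:", length(object@labels), "metabolites in",
        object@k, "clusters\n")
    best <- object@silhouette[object@silhouette$k == object@k, ]
    cat(sprintf("  mean silhouette at k*=%d: %.3f (%d repeats, seed %d)\n",
                object@k, best$mean, nrow(object@silhouetteRepeats),
                object@seed))
    print(table(cluster = object@labels))
})

#' @describeIn ModuleSet named list of member sets, module id -> names.
#' @export
setMethod("moduleMembers", "ModuleSet", function(x) x@modules)

#' @describeIn ModuleSet the underlying `hclust` tree.
#' @export
setMethod("moduleTree", "ModuleSet", function(x) x@tree)

setMethod("length", "ModuleSet", function(x) length(x@modules))

setMethod("show", "ModuleSet", function(object) {
    cat("ModuleSet:", length(object@modules), "candidate modules (min size",
        object@minSize, ")\n")
    if (length(object@modules)) {
        sz <- lengths(object@modules)
        cat("  sizes:", paste(range(sz), collapse = ".."),
            "| leaves:", length(object@tree$labels), "\n")
    }
})

#' @describeIn EigenMetabolites modules x samples score matrix.
#' @export
setMethod("eigenScores", "EigenMetabolites", function(x) x@scores)

#' @describeIn EigenMetabolites per-module fraction of variance explained.
#' @export
setMethod("varianceExplained", "EigenMetabolites", function(x) x@varianceExplained)

#' @describeIn EigenMetabolites per-module mean member correlation with the
#'   eigen-metabolite.
#' @export
setMethod("memberCorrelations", "EigenMetabolites", function(x) x@memberCorrelations)

#' @describeIn EigenMetabolites member sets of the retained modules.
#' @export
setMethod("moduleMembers", "EigenMetabolites", function(x) x@members)

setMethod("show", "EigenMetabolites", function(object) {
    cat("EigenMetabolites:", nrow(object@scores), "modules x",
        ncol(object@scores), "samples\n")
    if (nrow(object@scores))
        cat(sprintf("  variance explained: %.2f..%.2f | mean member cor: %.2f\n",
                    min(object@varianceExplained), max(object@varianceExplained),
                    mean(object@memberCorrelations)))
})

#' @describeIn Metabocard the HMDB accession.
#' @export
setMethod("hmdbId", "Metabocard", function(x) x@hmdbId)

setMethod("show", "Metabocard", function(object) {
    cat("Metabocard", object@hmdbId, "-", object@names[1], "\n")
    cat("  formula:", ifelse(nzchar(object@formula), object@formula, "<none>"),
        "| average mass:", object@averageMass, "\n")
    cat("  substituents:", length(object@substituents),
        "| enzymes:", length(object@enzymes),
        "| diseases:", length(object@diseases),
        "| pathways:", length(object@pathways), "\n")
})
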