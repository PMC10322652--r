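#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MetaboSet: a metabolite panel with aligned concentrations
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] with rows
#' as metabolites and columns as samples. The `"concentration"` assay holds
#' the measured intensities (arbitrary units, possibly `NA`); `rowData`
#' carries the panel fields `smiles`, `hmdb_id` and `valid` (whether the
#' SMILES parsed); `colData` carries the per-sample `group` factor.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [MetaboSet()] the constructor, [readPanel()] for file input.
#' @export
setClass("MetaboSet", contains = "SummarizedExperiment")

setValidity("MetaboSet", function(object) {
    msg <- NULL
    rd <- SummarizedExperiment::rowData(object)
    need <- c("smiles", "hmdb_id", "valid")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "metabolite names must be unique")
    if (is.null(rownames(object)) || any(!nzchar(rownames(object))))
        msg <- c(msg, "metabolite names must be non-empty")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if ("hmdb_id" %in% colnames(rd)) {
        id <- as.character(rd$hmdb_id)
        bad <- nzchar(id) & !grepl("^HMDB[0-9]+$", id)
        if (any(bad))
            msg <- c(msg, "hmdb_id must be empty or match 'HMDB' followed by digits")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MetaboSet from a panel table and a concentration matrix
#'
#' @param panel data.frame with columns `name`, `smiles`, `hmdb_id` (one row
#'   per metabolite). Names are trimmed of surrounding whitespace and must be
#'   unique and non-empty.
#' @param concentrations numeric matrix, samples x metabolites, with column
#'   names matching the panel `name`s (any order; reordered to panel order).
#' @param group per-sample group labels (factor or character), length equal
#'   to `nrow(concentrations)`.
#' @param validate logical; re-check that every SMILES parses (via OpenBabel
#'   canonicalization). When `FALSE`, a `valid` column already present in
#'   `panel` is used, else all records are taken as valid.
#'
#' @return A [MetaboSet-class] object. Metabolites whose SMILES fail to parse
#'   are retained with `valid = FALSE` and a message reports the count; they
#'   are excluded from fingerprint-based computations downstream.
#' @examples
#' pan <- data.frame(name = c("a", "b", "c"),
#'                   smiles = c("CCO", "CCCO", "CCCCO"),
#'                   hmdb_id = c("HMDB0000001", "", ""))
#' conc <- matrix(rlnorm(12), 4, 3, dimnames = list(NULL, pan$name))
#' ms <- MetaboSet(pan, conc, group = rep(c("A", "B"), each = 2))
#' @export
MetaboSet <- function(panel, concentrations, group, validate = TRUE) {
    panel <- as.data.frame(panel)
    need <- c("name", "smiles", "hmdb_id")
    miss <- setdiff(need, colnames(panel))
    if (length(miss))
        stop("panel is missing required column(s): ", paste(miss, collapse = ", "))
    panel$name <- trimws(as.character(panel$name))
    if (any(!nzchar(panel$name))) stop("panel contains empty metabolite names")
    if (anyDuplicated(panel$name))
        stop("duplicate metabolite names in panel: ",
             paste(unique(panel$name[duplicated(panel$name)]), collapse = ", "))
    panel$smiles <- as.character(panel$smiles)
    panel$hmdb_id <- as.character(panel$hmdb_id)
    panel$hmdb_id[is.na(panel$hmdb_id)] <- ""
    badId <- nzchar(panel$hmdb_id) & !grepl("^HMDB[0-9]+$", panel$hmdb_id)
    if (any(badId)) {
        warning("blanking ", sum(badId), " malformed HMDB accession(s): ",
                paste(utils::head(panel$hmdb_id[badId], 5), collapse = ", "))
        panel$hmdb_id[badId] <- ""
    }

    concentrations <- as.matrix(concentrations)
    if (!all(panel$name %in% colnames(concentrations)))
        stop("concentration matrix lacks column(s) for: ",
             paste(setdiff(panel$name, colnames(concentrations)), collapse = ", "))
    concentrations <- concentrations[, panel$name, drop = FALSE]
    if (length(group) != nrow(concentrations))
        stop("length(group) must equal the number of samples")
    if (!is.factor(group)) group <- factor(group, levels = unique(group))
    if (nlevels(group) < 1L) stop("group must have at least one level")

    if (validate) {
        can <- canonicalizeSmiles(panel$smiles)
        valid <- !is.na(can)
        if (any(!valid))
            message(sum(!valid), " metabolite(s) excluded from structural analysis ",
                    "(unparseable SMILES): ",
                    paste(utils::head(panel$name[!valid], 5), collapse = ", "))
    } else if ("valid" %in% colnames(panel)) {
        valid <- as.logical(panel$valid)
    } else {
        valid <- rep(TRUE, nrow(panel))
    }

    allNA <- apply(concentrations, 2, function(x) all(is.na(x)))
    if (any(allNA))
        stop("metabolite(s) with entirely missing concentrations: ",
             paste(panel$name[allNA], collapse = ", "))

    sampleIds <- rownames(concentrations)
    if (is.null(sampleIds)) sampleIds <- paste0("sample_", seq_len(nrow(concentrations)))

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(concentration = t(concentrations)),
        rowData = S4Vectors::DataFrame(smiles = panel$smiles,
                                       hmdb_id = panel$hmdb_id,
                                       valid = valid,
                                       row.names = panel$name),
        colData = S4Vectors::DataFrame(group = group, row.names = sampleIds))
    methods::new("MetaboSet", se)
}

#' Structural clustering result
#'
#' Holds the outcome of [detectClusters()]: the Tanimoto dissimilarities, the
#' multidimensional-scaling coordinates, a representative 2-D
#' accuracy-maximization embedding, the repeat-averaged silhouette profile,
#' the co-association matrix across repeats and the consensus cluster labels.
#'
#' @slot labels named integer vector, consensus cluster label per metabolite.
#' @slot k integer, selected number of clusters.
#' @slot silhouette data.frame with columns `k`, `mean`, `sd`.
#' @slot silhouetteRepeats numeric matrix, repeats x k values.
#' @slot embedding numeric matrix (n x 2), representative 2-D embedding
#'   (first repeat).
#' @slot mds list with `coords` and `eigenvalues` from [mdsEmbed()].
#' @slot dissimilarity numeric matrix of Tanimoto dissimilarities.
#' @slot coassociation numeric matrix, fraction of repeats in which each pair
#'   shared a cluster.
#' @slot dendrogram the consensus `hclust` tree (average linkage on
#'   1 - co-association).
#' @slot seed integer master seed.
#' @slot params list of tuning parameters used.
#' @export
setClass("StructuralClustering",
    representation(labels = "integer", k = "integer",
                   silhouette = "data.frame", silhouetteRepeats = "matrix",
                   embedding = "matrix", mds = "list",
                   dissimilarity = "matrix", coassociation = "matrix",
                   dendrogram = "ANY", seed = "integer", params = "list"))

setValidity("StructuralClustering", function(object) {
    msg <- NULL
    if (length(object@labels) &&
        !setequal(unique(object@labels), seq_len(object@k)))
        msg <- c(msg, "labels must cover 1..k with no empty cluster")
    s <- object@silhouette$mean
    if (length(s) && any(s < -1 - 1e-12 | s > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "silhouette values must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Candidate metabolite modules from dendrogram branches
#'
#' One candidate module per internal dendrogram node whose leaf set has at
#' least `minSize` members; module numbering follows a depth-first traversal
#' from the root, so identifiers are stable for a fixed tree.
#'
#' @slot modules named list, module id -> character vector of member names.
#' @slot tree the `hclust` object the branches were cut from.
#' @slot minSize integer minimum branch size.
#' @seealso [allBranches()]
#' @export
setClass("ModuleSet",
    representation(modules = "list", tree = "ANY", minSize = "integer"))

setValidity("ModuleSet", function(object) {
    msg <- NULL
    if (length(object@modules)) {
        sizes <- lengths(object@modules)
        if (any(sizes < object@minSize))
            msg <- c(msg, "every module must have >= minSize members")
        if (is.null(names(object@modules)))
            msg <- c(msg, "modules must be named by id")
    }
    if (is.null(msg)) TRUE else msg
})

#' Eigen-metabolite summaries of a module set
#'
#' Each module is summarized by its eigen-metabolite: the first principal
#' component of the standardized member concentration profiles. Score rows
#' have zero mean over samples and are oriented so that the mean correlation
#' with member profiles is non-negative.
#'
#' @slot scores numeric matrix, modules x samples.
#' @slot varianceExplained numeric, per-module fraction of variance carried
#'   by the first component, in (0, 1].
#' @slot memberCorrelations numeric, per-module mean correlation of member
#'   profiles with the eigen-metabolite.
#' @slot members named list of member names per retained module.
#' @seealso [wmcsaSummarize()], [eigenMetabolite()]
#' @export
setClass("EigenMetabolites",
    representation(scores = "matrix", varianceExplained = "numeric",
                   memberCorrelations = "numeric", members = "list"))

setValidity("EigenMetabolites", function(object) {
    msg <- NULL
    ve <- object@varianceExplained
    if (length(ve) && any(ve <= 0 | ve > 1 + 1e-12))
        msg <- c(msg, "varianceExplained must lie in (0, 1]")
    if (length(object@memberCorrelations) &&
        any(object@memberCorrelations < -1e-12))
        msg <- c(msg, "mean member correlations must be >= 0 (sign convention)")
    if (nrow(object@scores) &&
        max(abs(rowMeans(object@scores))) > 1e-8)
        msg <- c(msg, "score rows must have zero mean over samples")
    if (is.null(msg)) TRUE else msg
})

#' An HMDB metabocard
#'
#' Structured view of one HMDB metabocard XML file: identity, chemical
#' properties, structural substituents, chemical taxonomy, and associated
#' enzymes, diseases and pathways. Fields absent from the card are empty,
#' never `NA`-crashing.
#'
#' @slot hmdbId HMDB accession (e.g. `"HMDB0000001"`).
#' @slot names character, primary name followed by synonyms.
#' @slot formula chemical formula string (may be empty).
#' @slot averageMass,monoisotopicMass numeric (NA when absent).
#' @slot substituents character set of substituent names.
#' @slot taxonomy named character with entries `kingdom`, `super_class`,
#'   `class`, `sub_class` (empty strings when absent).
#' @slot enzymes character set of associated protein/gene names.
#' @slot diseases character set of disease names.
#' @slot pathways character set of pathway names.
#' @seealso [readMetabocard()]
#' @export
setClass("Metabocard",
    representation(hmdbId = "character", names = "character",
                   formula = "character", averageMass = "numeric",
                   monoisotopicMass = "numeric", substituents = "character",
                   taxonomy = "character", enzymes = "character",
                   diseases = "character", pathways = "character"))

setValidity("Metabocard", function(object) {
    msg <- NULL
    if (!grepl("^HMDB[0-9]+$", object@hmdbId))
        msg <- c(msg, "hmdbId must match 'HMDB' followed by digits")
    if (!is.na(object@averageMass) && object@averageMass <= 0)
        msg <- c(msg, "averageMass must be positive when present")
    if (!is.na(object@monoisotopicMass) && object@monoisotopicMass <= 0)
        msg <- c(msg, "monoisotopicMass must be positive when present")
    if (is.null(msg)) TRUE else msg
})
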