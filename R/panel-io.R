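#' Read a metabolite panel and its concentration matrix
#'
#' Reads two comma-separated files with headers: a panel table (columns
#' `name`, `smiles`, `hmdb_id`) and a concentration table (columns
#' `sample_id`, `group`, then one column per metabolite). Metabolite names
#' are matched case-sensitively after trimming whitespace. Concentration
#' columns absent from the panel — and panel records absent from the
#' concentration table — are dropped with a warning; zero overlap is an
#' error. Records whose SMILES fail to parse are retained with
#' `valid = FALSE` (and a reported count) and excluded from structural
#' computations downstream. Missing concentration values are kept as `NA`;
#' see [imputeConcentrations()].
#'
#' @param panelPath,concPath paths to the two CSV files.
#' @return a [MetaboSet-class].
#' @seealso [writePanel()] for the inverse operation.
#' @export
readPanel <- function(panelPath, concPath) {
    if (!file.exists(panelPath)) .stopf("panel file not found: %s", panelPath)
    if (!file.exists(concPath)) .stopf("concentration file not found: %s", concPath)
    panel <- utils::read.csv(panelPath, check.names = FALSE,
                             colClasses = "character")
    for (col in c("name", "smiles", "hmdb_id"))
        if (!col %in% colnames(panel))
            .stopf("panel file is missing required column '%s'", col)
    conc <- utils::read.csv(concPath, check.names = FALSE)
    for (col in c("sample_id", "group"))
        if (!col %in% colnames(conc))
            .stopf("concentration file is missing required column '%s'", col)

    panel$name <- trimws(panel$name)
    metCols <- setdiff(colnames(conc), c("sample_id", "group"))
    metNames <- trimws(metCols)
    shared <- intersect(panel$name, metNames)
    if (!length(shared))
        .stopf("no overlap between panel names and concentration columns")
    extra <- setdiff(metNames, panel$name)
    if (length(extra))
        warning("dropping ", length(extra),
                " concentration column(s) absent from the panel: ",
                paste(utils::head(extra, 5), collapse = ", "))
    orphan <- setdiff(panel$name, metNames)
    if (length(orphan))
        warning("dropping ", length(orphan),
                " panel record(s) without concentration data: ",
                paste(utils::head(orphan, 5), collapse = ", "))
    panel <- panel[panel$name %in% shared, , drop = FALSE]

    m <- as.matrix(conc[, metCols, drop = FALSE])
    mode(m) <- "numeric"
    colnames(m) <- metNames
    rownames(m) <- as.character(conc$sample_id)
    m <- m[, panel$name, drop = FALSE]
    MetaboSet(panel, m, group = conc$group)
}

#' Write a metabolite panel and its concentration matrix
#'
#' Inverse of [readPanel()]: writes the panel CSV (`name`, `smiles`,
#' `hmdb_id`) and the concentration CSV (`sample_id`, `group`, one column
#' per metabolite) so that reading them back reproduces the object
#' field-for-field.
#'
#' @param x a [MetaboSet-class].
#' @param panelPath,concPath output paths.
#' @return invisibly, `x`.
#' @export
writePanel <- function(x, panelPath, concPath) {
    stopifnot(is(x, "MetaboSet"))
    panel <- data.frame(name = rownames(x),
                        smiles = as.character(smiles(x)),
                        hmdb_id = as.character(hmdbId(x)))
    utils::write.csv(panel, panelPath, row.names = FALSE, quote = TRUE)
    conc <- data.frame(sample_id = colnames(x),
                       group = as.character(sampleGroups(x)),
                       check.names = FALSE)
    conc <- cbind(conc, as.data.frame(t(concentrations(x)),
                                      check.names = FALSE))
    utils::write.csv(conc, concPath, row.names = FALSE, quote = TRUE)
    invisible(x)
}

#' Impute missing concentrations
#'
#' Floor-style per-metabolite imputation of missing values, the common
#' metabolomics convention for sub-detection-limit intensities: each
#' metabolite's `NA`s are replaced by the minimum (or median) of its
#' observed values. With `method = "none"` any remaining `NA` is an error.
#'
#' @param x a [MetaboSet-class].
#' @param method `"min"` (default), `"median"`, or `"none"`.
#' @return `x` with an imputed `"concentration"` assay; a message reports
#'   how many values were imputed.
#' @export
imputeConcentrations <- function(x, method = c("min", "median", "none")) {
    stopifnot(is(x, "MetaboSet"))
    method <- match.arg(method)
    m <- concentrations(x)
    nmiss <- sum(is.na(m))
    if (method == "none") {
        if (nmiss > 0)
            .stopf("%d missing concentration value(s) and imputation disabled",
                   nmiss)
        return(x)
    }
    if (nmiss > 0) {
        f <- if (method == "min") function(v) min(v, na.rm = TRUE)
             else function(v) stats::median(v, na.rm = TRUE)
        for (i in which(rowSums(is.na(m)) > 0L))
            m[i, is.na(m[i, ])] <- f(m[i, ])
        message("imputed ", nmiss, " missing value(s) by per-metabolite ",
                method)
        SummarizedExperiment::assay(x, "concentration") <- m
    }
    x
}
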