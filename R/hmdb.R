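#' Read an HMDB metabocard XML file
#'
#' Parses one metabocard (the per-metabolite XML record distributed by
#' hmdb.ca, v4/v5 element names) into a structured [Metabocard-class].
#' Absent blocks yield empty fields, never an error; both the historical
#' `monisotopic_molecular_weight` spelling and the corrected
#' `monoisotopic_molecular_weight` are recognized.
#'
#' @param path path to a metabocard XML file whose root element is
#'   `<metabolite>`.
#' @return a [Metabocard-class].
#' @export
readMetabocard <- function(path) {
    if (!file.exists(path)) .stopf("metabocard file not found: %s", path)
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
        .stopf("malformed metabocard XML in %s: %s", path,
               conditionMessage(e)))
    doc <- xml2::xml_ns_strip(doc)
    if (xml2::xml_name(doc) != "metabolite")
        .stopf("not a metabocard: root element of %s is <%s>, expected <metabolite>",
               path, xml2::xml_name(doc))

    txt1 <- function(xp) {
        node <- xml2::xml_find_first(doc, xp)
        if (inherits(node, "xml_missing")) "" else trimws(xml2::xml_text(node))
    }
    txtAll <- function(xp) {
        v <- trimws(xml2::xml_text(xml2::xml_find_all(doc, xp)))
        unique(v[nzchar(v)])
    }
    num1 <- function(xp) {
        v <- suppressWarnings(as.numeric(txt1(xp)))
        if (length(v) == 0L || is.na(v)) NA_real_ else v
    }

    accession <- txt1("./accession")
    if (!grepl("^HMDB[0-9]+$", accession))
        .stopf("metabocard %s has missing or malformed <accession>", path)
    mono <- num1("./monisotopic_molecular_weight")
    if (is.na(mono)) mono <- num1("./monoisotopic_molecular_weight")

    taxonomy <- c(kingdom = txt1("./taxonomy/kingdom"),
                  super_class = txt1("./taxonomy/super_class"),
                  class = txt1("./taxonomy/class"),
                  sub_class = txt1("./taxonomy/sub_class"))
    enzymes <- unique(c(txtAll("./protein_associations/protein/gene_name"),
                        txtAll("./protein_associations/protein/name")))

    methods::new("Metabocard",
                 hmdbId = accession,
                 names = unique(c(txt1("./name"),
                                  txtAll("./synonyms/synonym"))),
                 formula = txt1("./chemical_formula"),
                 averageMass = num1("./average_molecular_weight"),
                 monoisotopicMass = mono,
                 substituents = txtAll("./taxonomy/substituents/substituent"),
                 taxonomy = taxonomy,
                 enzymes = enzymes,
                 diseases = txtAll("./diseases/disease/name"),
                 pathways = txtAll("./biological_properties/pathways/pathway/name"))
}

#' Read a directory (or set) of metabocards
#'
#' @param paths a directory containing `.xml` metabocards, or a character
#'   vector of file paths.
#' @return named list of [Metabocard-class] objects, keyed by accession.
#'   Duplicate accessions keep the last card, with a warning.
#' @export
readMetabocards <- function(paths) {
    if (length(paths) == 1L && dir.exists(paths))
        paths <- list.files(paths, pattern = "\\.xml$", full.names = TRUE)
    if (!length(paths)) .stopf("no metabocard XML files found")
    cards <- lapply(paths, readMetabocard)
    ids <- vapply(cards, hmdbId, character(1))
    if (anyDuplicated(ids)) {
        warning("duplicate metabocard accession(s), keeping the last: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
        cards <- cards[!duplicated(ids, fromLast = TRUE)]
        ids <- ids[!duplicated(ids, fromLast = TRUE)]
    }
    stats::setNames(cards, ids)
}

.attributeKinds <- c("substituent", "taxonomy", "enzyme", "disease", "pathway")

#' Extract an attribute table from metabocards
#'
#' Collects one kind of metabocard attribute across cards into a table
#' mapping each metabolite to its set of attribute values. Taxonomy values
#' are encoded as `"rank:value"` entries over the four ranks kingdom,
#' super_class, class and sub_class. Metabolites without a card are simply
#' absent from the table.
#'
#' @param cards list of [Metabocard-class] (see [readMetabocards()]).
#' @param kind one of `"substituent"`, `"taxonomy"`, `"enzyme"`,
#'   `"disease"`, `"pathway"`.
#' @param panel optional [MetaboSet-class]; when given, the table is keyed
#'   by panel metabolite name (via the panel's HMDB accessions) instead of
#'   by accession, and restricted to panel metabolites.
#' @return named list of character vectors (the attribute sets), with
#'   attribute `"kind"`.
#' @export
extractAttributes <- function(cards, kind, panel = NULL) {
    if (length(kind) != 1L || !kind %in% .attributeKinds)
        .stopf("unknown attribute kind '%s'; expected one of: %s",
               paste(kind, collapse = ","),
               paste(.attributeKinds, collapse = ", "))
    if (!length(cards)) .stopf("need at least one metabocard")
    ids <- vapply(cards, hmdbId, character(1))
    if (anyDuplicated(ids)) {
        warning("duplicate accession(s) among cards, keeping the last")
        cards <- cards[!duplicated(ids, fromLast = TRUE)]
        ids <- ids[!duplicated(ids, fromLast = TRUE)]
    }
    vals <- lapply(cards, function(cc) {
        switch(kind,
               substituent = cc@substituents,
               taxonomy = {
                   tx <- cc@taxonomy[nzchar(cc@taxonomy)]
                   if (length(tx)) paste0(names(tx), ":", tx) else character(0)
               },
               enzyme = cc@enzymes,
               disease = cc@diseases,
               pathway = cc@pathways)
    })
    names(vals) <- ids
    if (!is.null(panel)) {
        stopifnot(is(panel, "MetaboSet"))
        acc <- hmdbId(panel)
        hit <- acc[nzchar(acc) & acc %in% ids]
        vals <- stats::setNames(vals[hit], names(hit))
    }
    structure(vals, kind = kind)
}

#' Module attribute enrichment
#'
#' For every module and every attribute value carried by at least two
#' metabolites of the universe, tests over-representation of the attribute
#' among module members by a one-sided Fisher's exact test on the 2x2 table
#' (in-module/has-attribute vs out/lacks), with Benjamini-Hochberg
#' adjustment over all (module, value) pairs. Metabolites of the universe
#' that are missing from the attribute table count as lacking every
#' attribute.
#'
#' @param modules a [ModuleSet-class] or named list of member-name vectors.
#' @param table attribute table from [extractAttributes()] (keys must be in
#'   the universe).
#' @param universe character vector of metabolite names in scope; must
#'   contain every module member. By convention this is the set of valid
#'   panel metabolites with a parsed card.
#' @return data.frame with columns `module_id`, `kind`, `value`, `a`, `b`,
#'   `c`, `d` (the 2x2 counts), `odds_ratio` (sample odds ratio, `Inf` when
#'   undefined by a zero margin), `p`, `p_adj`.
#' @export
featureEnrichment <- function(modules, table, universe) {
    mods <- if (is(modules, "ModuleSet")) moduleMembers(modules) else modules
    universe <- unique(as.character(universe))
    if (!length(universe)) .stopf("empty universe")
    if (!length(mods)) .stopf("empty module set")
    if (is.null(names(mods))) names(mods) <- as.character(seq_along(mods))
    outside <- setdiff(unlist(mods), universe)
    if (length(outside))
        .stopf("module member(s) outside the universe: %s",
               paste(utils::head(outside, 5), collapse = ", "))
    strays <- setdiff(names(table), universe)
    if (length(strays)) table <- table[setdiff(names(table), strays)]
    kind <- attr(table, "kind")
    if (is.null(kind)) kind <- "attribute"

    # attribute -> carriers, keeping only values seen in >= 2 universe members
    carriers <- list()
    for (met in names(table))
        for (v in table[[met]])
            carriers[[v]] <- c(carriers[[v]], met)
    carriers <- lapply(carriers, unique)
    carriers <- carriers[lengths(carriers) >= 2L]
    if (!length(carriers))
        return(data.frame(module_id = character(0), kind = character(0),
                          value = character(0), a = integer(0), b = integer(0),
                          c = integer(0), d = integer(0),
                          odds_ratio = numeric(0), p = numeric(0),
                          p_adj = numeric(0)))
    N <- length(universe)
    rows <- list()
    for (mid in names(mods)) {
        inMod <- intersect(mods[[mid]], universe)
        for (v in names(carriers)) {
            has <- carriers[[v]]
            a <- length(intersect(inMod, has))
            b <- length(inMod) - a
            cc <- length(has) - a
            d <- N - a - b - cc
            p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L),
                                    alternative = "greater")$p.value
            orr <- if (b * cc == 0) {
                if (a * d == 0) 1 else Inf
            } else (a * d) / (b * cc)
            rows[[length(rows) + 1L]] <-
                data.frame(module_id = mid, kind = kind, value = v,
                           a = a, b = b, c = cc, d = d,
                           odds_ratio = orr, p = p)
        }
    }
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}
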