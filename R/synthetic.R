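#' Generate a structurally grouped synthetic metabolite panel
#'
#' Builds SMILES by homologous-series templating within each family —
#' straight-chain fatty acids, alkyl alpha-amino acids, N-alkyl imidazoles
#' and linear sugar alcohols — so that, like real chemical classes, members
#' of a family are mutually similar (graded by chain length) while families
#' are structurally distant. Every generated SMILES is valid by
#' construction and verified to parse.
#'
#' @param nPerFamily members per family (>= 3).
#' @param families character subset of `"fattyAcid"`, `"aminoAcid"`,
#'   `"imidazole"`, `"sugarAlcohol"` (>= 2 families).
#' @param seed integer master seed, recorded in the truth object (the
#'   series themselves are deterministic).
#' @return list with `panel` (data.frame `name`, `smiles`, `hmdb_id`) and
#'   `truth` (family per metabolite, planted modules — by default one per
#'   family, covering the family — their effect sizes in noise-SD units,
#'   per-module latent-score SDs, and the master seed).
#' @examples
#' gen <- generateStructuralPanel(4, seed = 1)
#' gen$panel$smiles
#' @export
generateStructuralPanel <- function(nPerFamily = 8L,
                                    families = c("fattyAcid", "aminoAcid",
                                                 "imidazole"),
                                    seed = 1L) {
    nPerFamily <- as.integer(nPerFamily)
    if (nPerFamily < 3L) .stopf("nPerFamily must be >= 3")
    known <- c("fattyAcid", "aminoAcid", "imidazole", "sugarAlcohol")
    bad <- setdiff(families, known)
    if (length(bad))
        .stopf("unknown family spec: %s (known: %s)",
               paste(bad, collapse = ", "), paste(known, collapse = ", "))
    if (length(families) < 2L) .stopf("need at least 2 families")

    series <- function(fam, i) {
        switch(fam,
               fattyAcid = paste0(strrep("C", 2L + i), "C(=O)O"),
               aminoAcid = sprintf("NC(%s)C(=O)O", strrep("C", i)),
               imidazole = sprintf("%sn1ccnc1", strrep("C", i)),
               sugarAlcohol = sprintf("OC%sCO", strrep("C(O)", i)))
    }
    prefix <- c(fattyAcid = "FA", aminoAcid = "AA", imidazole = "IM",
                sugarAlcohol = "SU")
    rows <- do.call(rbind, lapply(families, function(fam) {
        i <- seq_len(nPerFamily)
        data.frame(name = sprintf("%s_%02d", prefix[[fam]], i),
                   smiles = vapply(i, function(j) series(fam, j),
                                   character(1)),
                   family = fam)
    }))
    rows$hmdb_id <- sprintf("HMDB%07d", 9000000L + seq_len(nrow(rows)))
    if (anyNA(canonicalizeSmiles(rows$smiles)))
        .stopf("internal error: generated SMILES failed to parse")

    modules <- split(rows$name, rows$family)[unique(rows$family)]
    names(modules) <- as.character(seq_along(modules))
    truth <- list(family = stats::setNames(rows$family, rows$name),
                  modules = modules,
                  effects = stats::setNames(rep(0, length(modules)),
                                            names(modules)),
                  latentSd = stats::setNames(rep(1, length(modules)),
                                             names(modules)),
                  seed = as.integer(seed))
    list(panel = rows[, c("name", "smiles", "hmdb_id")], truth = truth)
}

#' Generate concentrations with planted module covariance and group effects
#'
#' Simulates a log-normal concentration matrix over the panel: on the log
#' scale, each planted module draws one latent per-sample score (SD
#' `truth$latentSd`, shared by its members with unit loading), members of a
#' module with a planted effect are shifted by `effect x noiseSd` in the
#' target group, and every metabolite receives independent Gaussian noise
#' of SD `noiseSd` around its own baseline. Non-members are pure
#' baseline-plus-noise. Values are exponentiated, so concentrations are
#' positive and log-normal, the standard model for metabolomics
#' intensities.
#'
#' @param panel data.frame from [generateStructuralPanel()] (or any with
#'   `name`, `smiles`, `hmdb_id`).
#' @param truth truth object from [generateStructuralPanel()]; its
#'   `modules` must be subsets of the panel, `effects` gives each module's
#'   group shift in noise-SD units, `latentSd` each module's latent-score
#'   SD (0 plants no shared co-variation).
#' @param nPerGroup samples per group (default 6, a typical small
#'   metabolomics design).
#' @param noiseSd log-scale measurement noise SD (> 0; default 0.3).
#' @param groups character vector of group levels (default
#'   `c("WT", "MYC")`); effects shift every level except the first.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return a [MetaboSet-class] with samples `<group>_<replicate>`.
#' @export
generateConcentrations <- function(panel, truth, nPerGroup = 6L,
                                   noiseSd = 0.3, groups = c("WT", "MYC"),
                                   seed = 1L) {
    if (noiseSd <= 0) .stopf("noiseSd must be > 0")
    nPerGroup <- as.integer(nPerGroup)
    if (nPerGroup < 1L) .stopf("nPerGroup must be >= 1")
    mets <- panel$name
    stray <- setdiff(unlist(truth$modules), mets)
    if (length(stray))
        .stopf("planted module member(s) not in panel: %s",
               paste(utils::head(stray, 5), collapse = ", "))
    nS <- nPerGroup * length(groups)
    grp <- factor(rep(groups, each = nPerGroup), levels = groups)
    shifted <- grp != groups[1L]

    m <- .withSeed(.deriveSeed(seed, 77L), {
        base <- stats::rnorm(length(mets), mean = 3, sd = 0.5)
        logc <- matrix(stats::rnorm(nS * length(mets), sd = noiseSd),
                       nrow = nS, ncol = length(mets)) +
                rep(base, each = nS)
        colnames(logc) <- mets
        for (mid in names(truth$modules)) {
            mem <- truth$modules[[mid]]
            lsd <- truth$latentSd[[mid]]
            if (lsd > 0) {
                z <- stats::rnorm(nS, sd = lsd)
                logc[, mem] <- logc[, mem] + z
            }
            eff <- truth$effects[[mid]]
            if (eff != 0)
                logc[shifted, mem] <- logc[shifted, mem] + eff * noiseSd
        }
        exp(logc)
    })
    rownames(m) <- paste0(grp, "_", sequence(rep(nPerGroup, length(groups))))
    MetaboSet(panel, m, group = grp, validate = FALSE)
}

# Miniature synthetic metabocard XML in the hmdb.ca layout; family-specific
# substituents/taxonomy/enzymes make enrichment detectable on fixtures.
.syntheticCardXml <- function(name, hmdb_id, family, smiles) {
    info <- switch(family,
        fattyAcid = list(sub = c("Carboxylic acid", "Alkyl chain"),
                         super = "Lipids and lipid-like molecules",
                         cls = "Fatty Acyls", subcls = "Fatty acids",
                         enz = c("ACOX1", "CPT1A"),
                         path = "Fatty acid beta-oxidation"),
        aminoAcid = list(sub = c("Alpha-amino acid", "Carboxylic acid"),
                         super = "Organic acids and derivatives",
                         cls = "Carboxylic acids and derivatives",
                         subcls = "Amino acids",
                         enz = c("GPT", "BCAT1"),
                         path = "Amino acid metabolism"),
        imidazole = list(sub = c("Imidazole", "Azole"),
                         super = "Organoheterocyclic compounds",
                         cls = "Azoles", subcls = "Imidazoles",
                         enz = c("HDC", "CNDP1"),
                         path = "Histidine metabolism"),
        sugarAlcohol = list(sub = c("Polyol", "Hydroxyl group"),
                            super = "Organic oxygen compounds",
                            cls = "Organooxygen compounds",
                            subcls = "Sugar alcohols",
                            enz = c("SORD", "AKR1B1"),
                            path = "Polyol pathway"),
        list(sub = "Organic compound", super = "Organic compounds",
             cls = "Other", subcls = "Other", enz = "ENZ1",
             path = "General metabolism"))
    nC <- nchar(gsub("[^Cc]", "", smiles))
    mass <- round(12.011 * nC + 18.015, 4)
    paste0(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
        "<metabolite>\n",
        "  <accession>", hmdb_id, "</accession>\n",
        "  <name>", name, "</name>\n",
        "  <synonyms>\n    <synonym>", name, " (synthetic)</synonym>\n",
        "  </synonyms>\n",
        "  <chemical_formula>C", nC, "H?O?</chemical_formula>\n",
        "  <average_molecular_weight>", mass, "</average_molecular_weight>\n",
        "  <monisotopic_molecular_weight>", mass,
        "</monisotopic_molecular_weight>\n",
        "  <smiles>", smiles, "</smiles>\n",
        "  <taxonomy>\n",
        "    <kingdom>Organic compounds</kingdom>\n",
        "    <super_class>", info$super, "</super_class>\n",
        "    <class>", info$cls, "</class>\n",
        "    <sub_class>", info$subcls, "</sub_class>\n",
        "    <substituents>\n",
        paste0("      <substituent>", info$sub, "</substituent>\n",
               collapse = ""),
        "    </substituents>\n",
        "  </taxonomy>\n",
        "  <biological_properties>\n",
        "    <pathways>\n      <pathway><name>", info$path,
        "</name></pathway>\n    </pathways>\n",
        "  </biological_properties>\n",
        "  <diseases>\n    <disease><name>Synthetic condition</name></disease>\n",
        "  </diseases>\n",
        "  <protein_associations>\n",
        paste0("    <protein><gene_name>", info$enz,
               "</gene_name><name>", info$enz,
               " protein</name></protein>\n", collapse = ""),
        "  </protein_associations>\n",
        "</metabolite>\n")
}

#' Write a self-contained fixture set to a directory
#'
#' Generates a panel, a concentration matrix and miniature metabocard XML
#' files (labelled synthetic; hmdb.ca layout), writing `panel.csv`,
#' `concentrations.csv`, `truth.json` and `metabocards/<accession>.xml`.
#'
#' @inheritParams generateStructuralPanel
#' @inheritParams generateConcentrations
#' @param dir output directory (created if needed).
#' @param nCards number of metabocards to write (default 5; use
#'   `nrow(panel)` for full annotation coverage).
#' @return invisibly, the list from [generateStructuralPanel()] plus the
#'   generated [MetaboSet-class] as `$mset`.
#' @export
writeFixtures <- function(dir, nPerFamily = 8L,
                          families = c("fattyAcid", "aminoAcid", "imidazole"),
                          nPerGroup = 6L, noiseSd = 0.3,
                          groups = c("WT", "MYC"), nCards = 5L, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gen <- generateStructuralPanel(nPerFamily, families, seed)
    mset <- generateConcentrations(gen$panel, gen$truth, nPerGroup, noiseSd,
                                   groups, seed)
    writePanel(mset, file.path(dir, "panel.csv"),
               file.path(dir, "concentrations.csv"))
    jsonlite::write_json(
        list(family = as.list(gen$truth$family),
             modules = gen$truth$modules,
             effects = as.list(gen$truth$effects),
             latent_sd = as.list(gen$truth$latentSd),
             seed = gen$truth$seed),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    cardDir <- file.path(dir, "metabocards")
    dir.create(cardDir, showWarnings = FALSE)
    nCards <- min(as.integer(nCards), nrow(gen$panel))
    for (i in seq_len(nCards)) {
        row <- gen$panel[i, ]
        fam <- gen$truth$family[[row$name]]
        writeLines(.syntheticCardXml(row$name, row$hmdb_id, fam, row$smiles),
                   file.path(cardDir, paste0(row$hmdb_id, ".xml")))
    }
    invisible(c(gen, list(mset = mset)))
}
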