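#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default:
#' fingerprint scheme (circular, radius 2, 1024 bits), 50 MDS dimensions,
#' 20 accuracy-maximization cycles, 10 embedding repeats, automatic `kmax`
#' (`min(30, n - 1)`), minimum module size 3, Mann-Whitney testing at
#' adjusted-p 0.05, per-metabolite minimum imputation, and one master seed
#' from which every stage seed is derived.
#'
#' @param panel,conc input CSV paths (see [readPanel()]).
#' @param out output directory.
#' @param cards optional directory of metabocard XML files ("" disables
#'   annotation).
#' @param scheme,bits,radius fingerprint scheme (see [fingerprintScheme()]).
#' @param dims,cycles,repeats,kmax clustering-stage tunables (see
#'   [detectClusters()]); `kmax = NA` selects the automatic cap.
#' @param minModuleSize smallest dendrogram branch reported as a module.
#' @param test,alpha,contrast differential-testing tunables (see
#'   [differentialModules()]); `contrast = ""` uses the first two group
#'   levels.
#' @param impute missing-value policy (see [imputeConcentrations()]).
#' @param seed integer master seed.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(panel, conc, out, cards = "",
                      scheme = "circular", bits = 1024L, radius = 2L,
                      dims = 50L, cycles = 20L, repeats = 10L, kmax = NA,
                      minModuleSize = 3L, test = "wilcox", alpha = 0.05,
                      contrast = "", impute = "min", seed = 1L) {
    cfg <- list(panel = panel, conc = conc, out = out, cards = cards,
                scheme = scheme, bits = as.integer(bits),
                radius = as.integer(radius), dims = as.integer(dims),
                cycles = as.integer(cycles), repeats = as.integer(repeats),
                kmax = if (is.na(kmax)) NA_integer_ else as.integer(kmax),
                minModuleSize = as.integer(minModuleSize), test = test,
                alpha = as.numeric(alpha), contrast = contrast,
                impute = impute, seed = as.integer(seed))
    class(cfg) <- c("RunConfig", "list")
    cfg
}

#' Read / write a run configuration
#'
#' `writeRunConfig()` serializes a [runConfig()] as `key = value` lines;
#' `readRunConfig()` reads either that format or a run `manifest.json`
#' (whose `config` block is used), so a finished run can be reproduced from
#' its manifest alone.
#'
#' @param config a `RunConfig`.
#' @param path file path.
#' @return `readRunConfig()` returns a `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
    lines <- vapply(names(config), function(k)
        sprintf("%s = %s", k, as.character(config[[k]])), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) .stopf("config file not found: %s", path)
    if (grepl("\\.json$", path)) {
        m <- jsonlite::read_json(path, simplifyVector = TRUE)
        raw <- if (!is.null(m$config)) m$config else m
    } else {
        lines <- readLines(path)
        lines <- lines[grepl("=", lines, fixed = TRUE)]
        keys <- trimws(sub("=.*$", "", lines))
        vals <- trimws(sub("^[^=]*=", "", lines))
        raw <- stats::setNames(as.list(vals), keys)
    }
    raw <- lapply(raw, function(v)
        if (is.null(v) || length(v) != 1L || is.na(v) ||
            identical(v, "NA")) NA else v)
    defaults <- formals(runConfig)
    args <- raw[names(raw) %in% names(defaults)]
    do.call(runConfig, args)
}

.configScheme <- function(config)
    fingerprintScheme(config$scheme, radius = config$radius,
                      bits = config$bits)

.configContrast <- function(config, groups) {
    if (nzchar(config$contrast)) {
        strsplit(config$contrast, ",", fixed = TRUE)[[1L]]
    } else if (nlevels(groups) >= 2L) {
        levels(groups)[1:2]
    } else NULL
}

.writeNum <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 17,
                                                   format = "g"))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

# Detection stage: structural clustering + its tabular outputs.
.stageDetect <- function(mset, config, outDir) {
    sc <- detectClusters(mset, scheme = .configScheme(config),
                         dims = config$dims, cycles = config$cycles,
                         repeats = config$repeats,
                         kmax = if (is.na(config$kmax)) NULL else config$kmax,
                         seed = config$seed)
    utils::write.csv(data.frame(name = names(clusterLabels(sc)),
                                cluster = unname(clusterLabels(sc))),
                     file.path(outDir, "clusters.csv"), row.names = FALSE)
    .writeNum(silhouetteProfile(sc),
              file.path(outDir, "silhouette_profile.csv"))
    emb <- embedding(sc)
    .writeNum(data.frame(name = rownames(emb), x = emb[, 1L], y = emb[, 2L]),
              file.path(outDir, "embedding.csv"))
    ape::write.tree(ape::as.phylo(sc@dendrogram),
                    file.path(outDir, "dendrogram_consensus.nwk"))
    sc
}

# Module stage over one cluster: branch modules, eigen-metabolites, tests.
.stageWmcsa <- function(mset, embedding, clusters, config, outDir) {
    groups <- sampleGroups(mset)
    contrast <- .configContrast(config, groups)
    membership <- list(); eigenRows <- list(); tests <- list()
    for (cid in sort(unique(clusters))) {
        members <- names(clusters)[clusters == cid]
        if (length(members) < max(2L, config$minModuleSize)) next
        hc <- stats::hclust(stats::dist(embedding[members, , drop = FALSE]),
                            method = "ward.D2")
        hc$labels <- members
        ms <- withCallingHandlers(
            allBranches(hc, minSize = config$minModuleSize),
            warning = function(w) invokeRestart("muffleWarning"))
        if (!length(ms)) next
        ape::write.tree(ape::as.phylo(hc),
                        file.path(outDir,
                                  sprintf("dendrogram_cluster_%s.nwk", cid)))
        em <- wmcsaSummarize(mset, ms, impute = config$impute)
        for (mid in names(moduleMembers(em)))
            membership[[length(membership) + 1L]] <-
                data.frame(cluster_id = cid, module_id = mid,
                           name = moduleMembers(em)[[mid]])
        sc <- eigenScores(em)
        eigenRows[[length(eigenRows) + 1L]] <-
            cbind(data.frame(cluster_id = cid, module_id = rownames(sc),
                             variance_explained = varianceExplained(em)),
                  as.data.frame(sc, check.names = FALSE))
        if (!is.null(contrast) &&
            all(table(groups)[contrast] >= 3L, na.rm = TRUE) &&
            all(contrast %in% levels(groups))) {
            dt <- differentialModules(em, groups, contrast,
                                      test = config$test,
                                      alpha = config$alpha)
            dt <- cbind(data.frame(cluster_id = cid), dt)
            tests[[length(tests) + 1L]] <- dt
        }
    }
    if (!length(membership))
        .stopf("no cluster yielded modules of size >= %d",
               config$minModuleSize)
    membership <- do.call(rbind, membership)
    utils::write.csv(membership, file.path(outDir, "module_membership.csv"),
                     row.names = FALSE)
    .writeNum(do.call(rbind, eigenRows),
              file.path(outDir, "eigen_metabolites.csv"))
    if (length(tests))
        .writeNum(do.call(rbind, tests),
                  file.path(outDir, "module_tests.csv"))
    membership
}

# Annotation stage: metabocard attributes + per-kind module enrichment.
.stageAnnotate <- function(mset, membership, cardsDir, outDir) {
    cards <- readMetabocards(cardsDir)
    acc <- hmdbId(mset)
    universe <- intersect(validMetabolites(mset),
                          names(acc)[acc %in% names(cards)])
    if (length(universe) < 2L)
        .stopf("fewer than 2 panel metabolites have a metabocard")
    mods <- split(membership$name,
                  paste0("c", membership$cluster_id, "_m",
                         membership$module_id))
    mods <- lapply(mods, intersect, universe)
    mods <- mods[lengths(mods) >= 2L]
    if (!length(mods)) .stopf("no module overlaps the annotated universe")
    out <- do.call(rbind, lapply(.attributeKinds, function(kind) {
        tab <- extractAttributes(cards, kind, panel = mset)
        featureEnrichment(mods, tab, universe)
    }))
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    .writeNum(out, file.path(outDir, "enrichment.csv"))
    out
}

#' Run the full pipeline
#'
#' Composes the published stage order — panel input, structural cluster
#' detection, branch-module summarization with differential testing, and
#' metabocard enrichment — writing all tabular outputs plus a
#' `manifest.json` (configuration, seed, versions) into the output
#' directory. Re-running from the same manifest reproduces every CSV
#' byte-identically.
#'
#' @param config a [runConfig()], or a path readable by [readRunConfig()].
#' @return invisibly, a list with the fitted objects and the output paths.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "RunConfig"))
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            .stopf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))

    # fail fast on parameters before any chemistry is computed
    stage("input", {
        if (!file.exists(config$panel))
            .stopf("panel file not found: %s", config$panel)
        if (!file.exists(config$conc))
            .stopf("concentration file not found: %s", config$conc)
        npanel <- nrow(utils::read.csv(config$panel))
        if (!is.na(config$kmax) && config$kmax >= npanel)
            .stopf("kmax (%d) must be smaller than the panel size (%d)",
                   config$kmax, npanel)
    })
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

    mset <- stage("input", readPanel(config$panel, config$conc))
    sc <- stage("detect", .stageDetect(mset, config, config$out))
    membership <- stage("wmcsa",
                        .stageWmcsa(mset, embedding(sc), clusterLabels(sc),
                                    config, config$out))
    enrich <- NULL
    if (nzchar(config$cards))
        enrich <- stage("annotate",
                        .stageAnnotate(mset, membership, config$cards,
                                       config$out))
    manifest <- list(config = unclass(config),
                     package = "MetaboModules",
                     package_version =
                         as.character(utils::packageVersion("MetaboModules")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."))
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(mset = mset, clustering = sc, membership = membership,
                   enrichment = enrich, out = config$out))
}
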