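#' Enumerate all dendrogram branches as candidate modules
#'
#' Every internal node of the tree whose leaf set has at least `minSize`
#' members defines one candidate module, so nested and overlapping modules
#' are all reported — ancestors are never pruned. Modules are numbered by a
#' depth-first preorder traversal from the root (left child before right),
#' which is stable for a fixed tree.
#'
#' @param tree an `hclust` object (e.g. a per-cluster structural dendrogram).
#' @param minSize smallest reported branch size (default 3; must be >= 2).
#' @return a [ModuleSet-class]; empty, with a warning, when `minSize`
#'   exceeds the leaf count.
#' @examples
#' hc <- hclust(dist(1:8), method = "average")
#' allBranches(hc, minSize = 2)
#' @export
allBranches <- function(tree, minSize = 3L) {
    if (!inherits(tree, "hclust")) .stopf("tree must be an hclust object")
    minSize <- as.integer(minSize)
    if (minSize < 2L) .stopf("minSize must be >= 2")
    n <- length(tree$labels)
    if (n < 2L) .stopf("tree must have at least 2 leaves")
    if (minSize > n) {
        warning("minSize (", minSize, ") exceeds the leaf count (", n,
                "); empty module set")
        return(methods::new("ModuleSet", modules = list(), tree = tree,
                            minSize = minSize))
    }
    merge <- tree$merge
    leafSets <- vector("list", nrow(merge))
    for (i in seq_len(nrow(merge))) {
        pick <- function(child)
            if (child < 0L) tree$labels[-child] else leafSets[[child]]
        leafSets[[i]] <- c(pick(merge[i, 1L]), pick(merge[i, 2L]))
    }
    # depth-first preorder from the root
    order <- integer(0)
    stack <- nrow(merge)
    while (length(stack)) {
        node <- stack[1L]
        stack <- stack[-1L]
        order <- c(order, node)
        kids <- merge[node, ]
        kids <- kids[kids > 0L]
        if (length(kids)) stack <- c(kids, stack)
    }
    keep <- order[lengths(leafSets[order]) >= minSize]
    modules <- leafSets[keep]
    names(modules) <- as.character(seq_along(modules))
    methods::new("ModuleSet", modules = modules, tree = tree,
                 minSize = minSize)
}

#' Eigen-metabolite of a module
#'
#' Summarizes a set of metabolites by the first principal component of
#' their standardized concentration profiles — the module eigen-metabolite.
#' Member profiles are standardized to zero mean and unit variance over
#' samples, the first right singular direction gives per-sample scores, and
#' the sign is chosen so the mean correlation between scores and member
#' profiles is non-negative. Scores therefore have zero mean over samples.
#'
#' @param x a [MetaboSet-class] with at least 3 samples.
#' @param members character vector of at least 2 metabolite names in `x`.
#' @param impute missing-value handling before the decomposition, see
#'   [imputeConcentrations()].
#' @param transform `"log"` (default) analyzes log-concentrations, the
#'   usual scale for metabolomics intensities; `"none"` uses the matrix as
#'   is. The log transform requires strictly positive values.
#' @return list with `scores` (named per-sample numeric),
#'   `varianceExplained` (first eigenvalue over the trace, in (0, 1]) and
#'   `memberCorrelation` (mean correlation of members with the score).
#'   Members constant across samples are dropped with a warning; fewer than
#'   2 surviving members is an error.
#' @export
eigenMetabolite <- function(x, members, impute = c("min", "median", "none"),
                            transform = c("log", "none")) {
    transform <- match.arg(transform)
    stopifnot(is(x, "MetaboSet"))
    members <- as.character(members)
    miss <- setdiff(members, rownames(x))
    if (length(miss))
        .stopf("module member(s) not in the panel: %s",
               paste(miss, collapse = ", "))
    if (length(members) < 2L) .stopf("a module needs at least 2 members")
    if (ncol(x) < 3L) .stopf("need at least 3 samples")
    x <- imputeConcentrations(x, match.arg(impute))
    M <- t(concentrations(x)[members, , drop = FALSE])  # samples x members
    if (transform == "log") {
        if (any(M <= 0))
            .stopf("log transform requires positive concentrations; use transform = 'none'")
        M <- log(M)
    }
    sds <- apply(M, 2L, stats::sd)
    if (any(sds == 0)) {
        warning("dropping constant member(s): ",
                paste(members[sds == 0], collapse = ", "))
        M <- M[, sds > 0, drop = FALSE]
        if (ncol(M) < 2L)
            .stopf("module degenerate: fewer than 2 non-constant members")
    }
    Z <- scale(M)
    sv <- svd(Z)
    scores <- sv$u[, 1L] * sv$d[1L]
    memberCor <- stats::cor(scores, Z)
    if (mean(memberCor) < 0) {
        scores <- -scores
        memberCor <- -memberCor
    }
    names(scores) <- colnames(x)
    list(scores = scores,
         varianceExplained = sv$d[1L]^2 / sum(sv$d^2),
         memberCorrelation = mean(memberCor))
}

#' Summarize all modules by their eigen-metabolites
#'
#' Applies [eigenMetabolite()] to every module of a [ModuleSet-class];
#' nested modules are summarized independently (no orthogonalization).
#' Degenerate modules (collapsing below 2 non-constant members) are dropped
#' with a message; an entirely degenerate module set is an error.
#'
#' @param x a [MetaboSet-class].
#' @param modules a [ModuleSet-class] (or named list of member vectors).
#' @inheritParams eigenMetabolite
#' @return an [EigenMetabolites-class] with one score row per surviving
#'   module.
#' @export
wmcsaSummarize <- function(x, modules, impute = c("min", "median", "none"),
                           transform = c("log", "none")) {
    impute <- match.arg(impute)
    transform <- match.arg(transform)
    mods <- if (is(modules, "ModuleSet")) moduleMembers(modules) else modules
    if (!length(mods)) .stopf("empty module set")
    if (is.null(names(mods))) names(mods) <- as.character(seq_along(mods))
    x <- imputeConcentrations(x, impute)
    res <- lapply(mods, function(mm)
        tryCatch(suppressWarnings(eigenMetabolite(x, mm, impute = "none",
                                                  transform = transform)),
                 error = function(e) NULL))
    ok <- !vapply(res, is.null, logical(1))
    if (!any(ok)) .stopf("all modules are degenerate")
    if (any(!ok))
        message("dropped ", sum(!ok), " degenerate module(s): ",
                paste(names(mods)[!ok], collapse = ", "))
    res <- res[ok]
    scores <- do.call(rbind, lapply(res, `[[`, "scores"))
    rownames(scores) <- names(mods)[ok]
    methods::new("EigenMetabolites",
                 scores = scores,
                 varianceExplained = vapply(res, `[[`, numeric(1),
                                            "varianceExplained"),
                 memberCorrelations = vapply(res, `[[`, numeric(1),
                                             "memberCorrelation"),
                 members = mods[ok])
}

#' Test modules for group differences
#'
#' Per-module two-group comparison of eigen-metabolite scores, by a
#' two-sided Mann-Whitney U test (default; robust at the small per-group
#' sizes typical of metabolomics designs) or Welch's t test, with
#' Benjamini-Hochberg adjustment across modules.
#'
#' @param E an [EigenMetabolites-class] or a modules x samples score matrix.
#' @param groups per-sample group labels (factor or character).
#' @param contrast character of two group levels, `c(reference, other)`;
#'   defaults to the first two levels. Each level needs >= 3 samples.
#' @param test `"wilcox"` (Mann-Whitney U) or `"welch"`.
#' @param alpha significance threshold on the adjusted p-value.
#' @return data.frame with one row per module: `module_id`, `statistic`,
#'   `p`, `p_adj`, `direction` (+1 when the second contrast level scores
#'   higher, -1 lower, 0 tied) and `significant`.
#' @export
differentialModules <- function(E, groups, contrast = NULL,
                                test = c("wilcox", "welch"), alpha = 0.05) {
    test <- match.arg(test)
    scores <- if (is(E, "EigenMetabolites")) eigenScores(E) else as.matrix(E)
    groups <- factor(groups)
    if (length(groups) != ncol(scores))
        .stopf("length(groups) must equal the number of samples")
    if (is.null(contrast)) {
        if (nlevels(groups) < 2L) .stopf("groups must have >= 2 levels")
        contrast <- levels(groups)[1:2]
    }
    miss <- setdiff(contrast, levels(groups))
    if (length(miss))
        .stopf("contrast level(s) not present: %s", paste(miss, collapse = ", "))
    i1 <- which(groups == contrast[1L])
    i2 <- which(groups == contrast[2L])
    if (length(i1) < 3L || length(i2) < 3L)
        .stopf("each contrast level needs at least 3 samples")
    out <- do.call(rbind, lapply(rownames(scores), function(mid) {
        a <- scores[mid, i1]
        b <- scores[mid, i2]
        ht <- if (test == "wilcox")
            suppressWarnings(stats::wilcox.test(b, a, exact = NULL))
        else
            stats::t.test(b, a)
        data.frame(module_id = mid,
                   statistic = unname(ht$statistic),
                   p = ht$p.value,
                   direction = sign(mean(b) - mean(a)))
    }))
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha
    out[, c("module_id", "statistic", "p", "p_adj", "direction",
            "significant")]
}
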