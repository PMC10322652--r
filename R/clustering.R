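#' Rousseeuw silhouette index of a partition
#'
#' Mean over points of `(b - a) / max(a, b)`, where `a` is the mean distance
#' to the point's own cluster and `b` the smallest mean distance to any
#' other cluster. Points in singleton clusters contribute 0, as do points
#' whose `a` and `b` are both zero (coincident clusters).
#'
#' @param coords numeric coordinate matrix (rows = points).
#' @param labels cluster labels, one per point; at least two distinct
#'   clusters, none empty.
#' @return the mean silhouette width, in `[-1, 1]`.
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 8), 10))
#' silhouetteIndex(x, rep(1:2, each = 10))
#' @export
silhouetteIndex <- function(coords, labels) {
    D <- as.matrix(stats::dist(as.matrix(coords)))
    .silhouetteFromDist(D, labels)
}

.silhouetteFromDist <- function(D, labels) {
    labels <- as.integer(factor(labels))
    n <- length(labels)
    if (nrow(D) != n) .stopf("labels length must match point count")
    k <- max(labels)
    if (k < 2L) .stopf("silhouette undefined for a single cluster")
    sizes <- tabulate(labels, k)
    if (any(sizes == 0L)) .stopf("every cluster must be non-empty")
    # mean distance from each point to each cluster
    sums <- matrix(0, n, k)
    for (g in seq_len(k))
        sums[, g] <- rowSums(D[, labels == g, drop = FALSE])
    s <- numeric(n)
    for (i in seq_len(n)) {
        g <- labels[i]
        if (sizes[g] == 1L) { s[i] <- 0; next }
        a <- sums[i, g] / (sizes[g] - 1L)
        b <- min(sums[i, -g] / sizes[-g])
        m <- max(a, b)
        s[i] <- if (m == 0) 0 else (b - a) / m
    }
    mean(s)
}

#' Detect structural metabolite clusters
#'
#' Runs the full structural-clustering chain: fingerprints, Tanimoto
#' dissimilarity, classical MDS, accuracy-maximization 2-D embedding, and
#' Ward hierarchical clustering. The stochastic embedding stage is repeated
#' (`repeats`, 10 by default) with derived seeds; for every repeat and every
#' `k` in `2..kmax` the tree is cut and the silhouette recorded, and the
#' number of clusters `k*` is the `k` maximizing the repeat-averaged
#' silhouette (ties break to the smallest `k`). Final labels are a consensus
#' over repeats: average-linkage clustering of the co-association matrix
#' (fraction of repeats in which two metabolites were co-clustered), cut at
#' `k*`.
#'
#' @param x a [MetaboSet-class] (valid records only) or a named character
#'   vector of SMILES.
#' @param scheme a [fingerprintScheme()].
#' @param dims MDS dimensions retained (default 50).
#' @param cycles accuracy-maximization cycles per repeat (default 20).
#' @param repeats number of embedding repeats averaged (default 10).
#' @param kmax largest number of clusters scanned; default
#'   `min(30, n - 1)`. Must be `< n`.
#' @param seed integer master seed.
#' @return a [StructuralClustering-class] object.
#' @examples
#' \donttest{
#' pan <- generateStructuralPanel(nPerFamily = 5, seed = 1)
#' sc <- detectClusters(pan$panel$smiles, repeats = 2, seed = 1)
#' }
#' @export
setGeneric("detectClusters",
    function(x, scheme = fingerprintScheme(), dims = 50L, cycles = 20L,
             repeats = 10L, kmax = NULL, seed = 1L)
        standardGeneric("detectClusters"))

#' @rdname detectClusters
#' @export
setMethod("detectClusters", "MetaboSet",
    function(x, scheme, dims, cycles, repeats, kmax, seed) {
        keep <- validMetabolites(x)
        detectClusters(smiles(x)[keep], scheme, dims, cycles, repeats,
                       kmax, seed)
    })

#' @rdname detectClusters
#' @export
setMethod("detectClusters", "character",
    function(x, scheme, dims, cycles, repeats, kmax, seed) {
        n <- length(x)
        if (n < 4L) .stopf("need at least 4 valid metabolites, got %d", n)
        if (is.null(kmax)) kmax <- min(30L, n - 1L)
        kmax <- as.integer(kmax)
        if (kmax >= n) .stopf("kmax (%d) must be smaller than the number of metabolites (%d)", kmax, n)
        if (kmax < 2L) .stopf("kmax must be >= 2")
        repeats <- as.integer(repeats)
        if (repeats < 1L) .stopf("repeats must be >= 1")
        if (is.null(names(x))) names(x) <- paste0("met_", seq_along(x))

        D <- dissimilarityMatrix(x, scheme)
        X <- mdsEmbed(D, dims)
        ks <- seq.int(2L, kmax)
        sil <- matrix(NA_real_, repeats, length(ks),
                      dimnames = list(NULL, paste0("k", ks)))
        cuts <- vector("list", repeats)
        E1 <- NULL
        for (r in seq_len(repeats)) {
            E <- kodamaEmbed(X, cycles = cycles,
                             seed = .deriveSeed(seed, 1000L + r))
            if (r == 1L) E1 <- E
            dE <- as.matrix(stats::dist(E))
            hc <- stats::hclust(stats::as.dist(dE), method = "ward.D2")
            cm <- stats::cutree(hc, k = ks)
            cuts[[r]] <- cm
            for (j in seq_along(ks))
                sil[r, j] <- .silhouetteFromDist(dE, cm[, j])
        }
        prof <- data.frame(k = ks,
                           mean = colMeans(sil),
                           sd = apply(sil, 2L, stats::sd))
        kstar <- ks[which.max(prof$mean)]

        co <- matrix(0, n, n)
        j <- match(kstar, ks)
        for (r in seq_len(repeats)) {
            lab <- cuts[[r]][, j]
            co <- co + outer(lab, lab, "==")
        }
        co <- co / repeats
        dimnames(co) <- list(names(x), names(x))
        hcons <- stats::hclust(stats::as.dist(1 - co), method = "average")
        labels <- stats::cutree(hcons, k = kstar)
        names(labels) <- names(x)

        methods::new("StructuralClustering",
                     labels = labels, k = as.integer(kstar),
                     silhouette = prof, silhouetteRepeats = sil,
                     embedding = E1, mds = X, dissimilarity = D,
                     coassociation = co, dendrogram = hcons,
                     seed = as.integer(seed),
                     params = list(scheme = scheme$id, dims = dims,
                                   cycles = cycles, repeats = repeats,
                                   kmax = kmax))
    })
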