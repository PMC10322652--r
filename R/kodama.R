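#' Accuracy-maximization proximity matrix
#'
#' Core of the KODAMA-style embedding: repeatedly partitions the points at
#' random and sharpens the partition by leave-one-out 1-nearest-neighbor
#' cross-validation, accepting label reassignments that increase the
#' cross-validated accuracy, until accuracy stops improving (at most
#' `maxInner` proposals per cycle). Across `cycles` independent restarts the
#' procedure accumulates, for every pair of points, the fraction of cycles
#' in which the two ended with the same label — a proximity in `[0, 1]`
#' whose entries lie exactly on the grid `{0, 1/cycles, ..., 1}`.
#'
#' Points with identical coordinates are indistinguishable to any
#' distance-based classifier and are constrained to share a label within
#' every cycle, so exact structural duplicates always reach proximity 1.
#'
#' @param X numeric coordinate matrix (rows = points), or the list returned
#'   by [mdsEmbed()].
#' @param cycles number of accuracy-maximization restarts (default 20).
#' @param seed integer master seed; per-cycle seeds are derived from it, so
#'   results are reproducible from this one number.
#' @param startClasses number of classes in the random initial partition.
#' @param maxInner cap on label-update proposals per cycle.
#' @return symmetric numeric proximity matrix with unit diagonal and
#'   attribute `"cycles"`.
#' @examples
#' X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' P <- accuracyMaximization(X, cycles = 5, seed = 1)
#' @export
accuracyMaximization <- function(X, cycles = 20L, seed = 1L,
                                 startClasses = 5L, maxInner = 20L) {
    if (is.list(X) && !is.null(X$coords)) X <- X$coords
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < 4L) .stopf("need at least 4 points, got %d", n)
    cycles <- as.integer(cycles)
    if (cycles < 1L) .stopf("cycles must be >= 1")

    # collapse exact duplicates: they must co-label
    key <- apply(X, 1L, paste, collapse = "\r")
    uniq <- !duplicated(key)
    map <- match(key, key[uniq])
    nU <- sum(uniq)

    P <- matrix(0, n, n)
    if (nU == 1L) {
        P[] <- cycles
    } else {
        D <- as.matrix(stats::dist(X[uniq, , drop = FALSE]))
        diag(D) <- Inf
        nn <- apply(D, 1L, which.min)
        revnn <- lapply(seq_len(nU), function(i) which(nn == i))
        for (cy in seq_len(cycles)) {
            lab <- .withSeed(.deriveSeed(seed, cy),
                             .accuracySharpen(nn, revnn, startClasses,
                                              maxInner))
            full <- lab[map]
            P <- P + outer(full, full, "==")
        }
    }
    P <- P / cycles
    diag(P) <- 1
    dimnames(P) <- list(rownames(X), rownames(X))
    attr(P, "cycles") <- cycles
    P
}

# One accuracy-maximization cycle: random startClasses-partition, then up to
# maxInner sweeps over the currently misclassified points (in random order),
# reassigning each to its leave-one-out 1-NN prediction whenever the move
# does not decrease the cross-validated accuracy. Flipping point i changes
# only its own correctness and that of points whose nearest neighbor is i,
# so accuracy is updated incrementally. Stops when a sweep changes nothing
# (accuracy has stopped increasing) or all points are consistent.
.accuracySharpen <- function(nn, revnn, startClasses, maxInner) {
    nU <- length(nn)
    lab <- sample.int(startClasses, nU, replace = TRUE)
    correct <- lab[nn] == lab
    for (it in seq_len(maxInner)) {
        mis <- which(!correct)
        if (!length(mis)) break
        changed <- FALSE
        for (i in mis[sample.int(length(mis))]) {
            new <- lab[nn[i]]
            if (new == lab[i]) next
            delta <- (new == lab[nn[i]]) - correct[i]  # own term: always +1 here
            js <- revnn[[i]]
            if (length(js)) delta <- delta + sum(lab[js] == new) - sum(correct[js])
            if (delta >= 0) {
                lab[i] <- new
                correct[i] <- TRUE
                if (length(js)) correct[js] <- lab[js] == new
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    lab
}

#' Two-dimensional accuracy-maximization embedding
#'
#' Converts the [accuracyMaximization()] proximity matrix to a
#' dissimilarity (`1 - p`) and embeds it in two dimensions by classical
#' multidimensional scaling, giving the "chemical distances" map on which
#' structural clusters are detected. Deterministic for a fixed seed.
#'
#' If fewer than two positive eigenvalues remain (e.g. a single tight blob
#' whose pairwise proximities are all 1), the missing axes are zero-filled
#' so the result is always n x 2.
#'
#' @inheritParams accuracyMaximization
#' @param ... passed on to [accuracyMaximization()] (`startClasses`,
#'   `maxInner`).
#' @return numeric n x 2 coordinate matrix, rows in input order.
#' @examples
#' X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' E <- kodamaEmbed(X, cycles = 5, seed = 1)
#' @export
kodamaEmbed <- function(X, cycles = 20L, seed = 1L, ...) {
    P <- accuracyMaximization(X, cycles = cycles, seed = seed, ...)
    n <- nrow(P)
    Dp <- 1 - P
    diag(Dp) <- 0
    coords <- matrix(0, n, 2L,
                     dimnames = list(rownames(P), c("x", "y")))
    if (max(Dp) > 0) {
        fit <- suppressWarnings(stats::cmdscale(Dp, k = min(2L, n - 1L),
                                                eig = TRUE))
        pts <- fit$points
        keep <- seq_len(min(2L, ncol(pts)))
        keep <- keep[fit$eig[keep] > max(abs(fit$eig)) * 1e-9]
        if (length(keep))
            coords[, seq_along(keep)] <- pts[, keep, drop = FALSE]
    }
    coords
}
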