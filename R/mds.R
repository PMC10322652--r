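#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Embeds a metabolite dissimilarity matrix into a multidimensional
#' coordinate space by classical (Torgerson) scaling, retaining at most
#' `dims` axes (50 by default) and truncating axes with non-positive
#' eigenvalues — Tanimoto dissimilarity matrices need not be Euclidean, so
#' the negative part of the spectrum is dropped rather than fitted.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal (e.g. from
#'   [dissimilarityMatrix()]).
#' @param dims maximum number of axes to retain (default 50).
#' @return list with `coords` (n x k matrix, k = min(dims, number of
#'   positive eigenvalues), axes ordered by descending eigenvalue, rows named
#'   as `D`) and `eigenvalues` (the k retained values).
#' @examples
#' d <- dissimilarityMatrix(c(a = "CCO", b = "CCCO", c = "c1ccccc1"))
#' fit <- mdsEmbed(d, dims = 2)
#' @export
mdsEmbed <- function(D, dims = 50L) {
    D <- as.matrix(D)
    if (nrow(D) != ncol(D)) .stopf("D must be square")
    if (max(abs(D - t(D))) > 1e-8) .stopf("D must be symmetric")
    if (max(abs(diag(D))) > 1e-8) .stopf("D must have a zero diagonal")
    dims <- as.integer(dims)
    if (dims < 1L) .stopf("dims must be >= 1")
    n <- nrow(D)
    fit <- suppressWarnings(stats::cmdscale(D, k = n - 1L, eig = TRUE))
    eig <- fit$eig
    tol <- max(abs(eig)) * 1e-9
    npos <- sum(eig > tol)
    if (npos == 0L)
        .stopf("degenerate dissimilarity matrix: no positive eigenvalues")
    k <- min(dims, npos, ncol(fit$points))
    coords <- fit$points[, seq_len(k), drop = FALSE]
    rownames(coords) <- rownames(D)
    colnames(coords) <- paste0("dim_", seq_len(k))
    list(coords = coords, eigenvalues = eig[seq_len(k)])
}
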