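#' Molecular fingerprint of set bits
#'
#' A sparse bit-set representation of a molecular fingerprint: `bits` holds
#' the 0-based positions of the set bits, `nbits` the total bit-vector
#' length, and `scheme` an identifier of the fingerprint family and its
#' parameters. Fingerprints are only comparable when their `nbits` and
#' `scheme` agree.
#'
#' @slot bits sorted integer vector of set-bit positions in `[0, nbits)`.
#' @slot nbits integer, total number of bits (> 0).
#' @slot scheme character scheme identifier, e.g. `"circular/r2/1024"`.
#' @seealso [smilesToFingerprint()], [tanimotoDissimilarity()]
#' @export
setClass("Fingerprint",
    representation(bits = "integer", nbits = "integer", scheme = "character"))

setValidity("Fingerprint", function(object) {
    msg <- NULL
    if (object@nbits <= 0L) msg <- c(msg, "nbits must be > 0")
    if (length(object@bits) &&
        (min(object@bits) < 0L || max(object@bits) >= object@nbits))
        msg <- c(msg, "bit positions must lie in [0, nbits)")
    if (is.unsorted(object@bits, strictly = TRUE))
        msg <- c(msg, "bits must be sorted and unique")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "Fingerprint", function(object) {
    cat(sprintf("Fingerprint [%s]: %d/%d bits set\n", object@scheme,
                length(object@bits), object@nbits))
})

#' Fingerprint scheme configuration
#'
#' The default scheme is a circular (extended-connectivity style)
#' fingerprint of radius 2 folded to 1024 bits, computed on the molecular
#' graph after OpenBabel canonicalization: atom environments of growing
#' radius are hashed from iteratively refined atom identifiers (element,
#' degree, bond-order sum, then neighbor identifiers), and every
#' environment's hash sets one bit. Path-based (`"fp2"`) and MACCS-key
#' (`"maccs"`) schemes are available through OpenBabel; note these encode no
#' bits for single-atom molecules.
#'
#' @param type one of `"circular"`, `"fp2"`, `"maccs"`.
#' @param radius circular-environment radius (circular scheme only).
#' @param bits bit-vector length (circular scheme only; fp2 is fixed at
#'   1024, maccs at 166).
#' @return a `FingerprintScheme` list with fields `type`, `radius`, `bits`
#'   and the identifier string `id`.
#' @examples
#' fingerprintScheme()
#' fingerprintScheme("maccs")
#' @export
fingerprintScheme <- function(type = c("circular", "fp2", "maccs"),
                              radius = 2L, bits = 1024L) {
    type <- match.arg(type)
    radius <- as.integer(radius)
    bits <- as.integer(bits)
    if (type == "circular") {
        if (radius < 0L) stop("radius must be >= 0")
        if (bits < 1L) stop("bits must be >= 1")
        id <- sprintf("circular/r%d/%d", radius, bits)
    } else if (type == "fp2") {
        bits <- 1024L
        id <- "fp2/1024"
    } else {
        bits <- 166L
        id <- "maccs/166"
    }
    structure(list(type = type, radius = radius, bits = bits, id = id),
              class = "FingerprintScheme")
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES, so that equivalent input
#' notations map to a single representation before fingerprint hashing.
#'
#' @param x character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' canonicalizeSmiles(c("CCO", "OCC", "not_a_smiles"))
#' @export
canonicalizeSmiles <- function(x) {
    x <- as.character(x)
    out <- rep(NA_character_, length(x))
    ok <- !is.na(x) & nzchar(trimws(x))
    if (!any(ok)) return(out)
    idx <- which(ok)
    tags <- sprintf("mm%d", idx)
    convert <- function(inp) {
        res <- tryCatch(
            suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", inp)),
            error = function(e) "")
        lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
        for (ln in lines[nzchar(lines)]) {
            parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
            if (length(parts) < 2L) next
            i <- match(trimws(parts[2L]), tags)
            if (!is.na(i) && nzchar(parts[1L])) out[idx[i]] <<- parts[1L]
        }
    }
    # batch first; OpenBabel stops at a parse failure, so finish the
    # stragglers one molecule at a time (they are usually the invalid ones)
    convert(paste0(paste(trimws(x[idx]), tags), "\n", collapse = ""))
    for (j in which(is.na(out[idx])))
        convert(paste0(trimws(x[idx[j]]), " ", tags[j], "\n"))
    out
}

# Molecular graph (elements + bond list) from canonical SMILES, via an
# OpenBabel SDF conversion whose V2000 molblock counts/atom/bond lines are
# read directly (fixed-width fields); this stays correct for single-atom
# molecules, where higher-level SDF containers degenerate. Returns a list
# per molecule with `elem` (character) and `bonds` (from, to, order).
.smilesGraphs <- function(canonical) {
    stopifnot(!anyNA(canonical))
    txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                     paste0(paste0(canonical, "\n"), collapse = ""))
    blocks <- strsplit(txt, "$$$$", fixed = TRUE)[[1L]]
    blocks <- blocks[vapply(blocks, function(b) grepl("V2000", b, fixed = TRUE),
                            logical(1))]
    if (length(blocks) != length(canonical))
        .stopf("SDF conversion returned %d molecule(s) for %d SMILES",
               length(blocks), length(canonical))
    lapply(blocks, function(b) {
        ln <- strsplit(b, "\n", fixed = TRUE)[[1L]]
        cl <- which(grepl("V2000", ln, fixed = TRUE))[1L]
        nA <- as.integer(substr(ln[cl], 1L, 3L))
        nB <- as.integer(substr(ln[cl], 4L, 6L))
        atomLn <- ln[cl + seq_len(nA)]
        elem <- trimws(substr(atomLn, 32L, 34L))
        if (nB > 0L) {
            bondLn <- ln[cl + nA + seq_len(nB)]
            bonds <- cbind(from = as.integer(substr(bondLn, 1L, 3L)),
                           to = as.integer(substr(bondLn, 4L, 6L)),
                           order = as.integer(substr(bondLn, 7L, 9L)))
        } else {
            bonds <- cbind(from = integer(0), to = integer(0), order = integer(0))
        }
        list(elem = elem, bonds = bonds)
    })
}

# Circular (Morgan-style) environment hashing of one molecular graph.
.circularBits <- function(graph, radius, nbits) {
    nA <- length(graph$elem)
    deg <- integer(nA)
    bsum <- integer(nA)
    nbr <- vector("list", nA)
    if (nrow(graph$bonds)) {
        for (r in seq_len(nrow(graph$bonds))) {
            i <- graph$bonds[r, 1L]; j <- graph$bonds[r, 2L]
            o <- graph$bonds[r, 3L]
            deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
            bsum[i] <- bsum[i] + o; bsum[j] <- bsum[j] + o
            nbr[[i]] <- rbind(nbr[[i]], c(o, j))
            nbr[[j]] <- rbind(nbr[[j]], c(o, i))
        }
    }
    ids <- vapply(seq_len(nA), function(i)
        .hashString(paste(graph$elem[i], deg[i], bsum[i], sep = "#")),
        numeric(1))
    all <- ids
    for (r in seq_len(radius)) {
        ids <- vapply(seq_len(nA), function(i) {
            if (is.null(nbr[[i]])) {
                env <- ""
            } else {
                parts <- sprintf("%d:%.0f", nbr[[i]][, 1L], ids[nbr[[i]][, 2L]])
                env <- paste(sort(parts), collapse = "|")
            }
            .hashString(paste(ids[i], env, sep = "@"))
        }, numeric(1))
        all <- c(all, ids)
    }
    sort(unique(as.integer(all %% nbits)))
}

# OpenBabel fingerprint bit positions for a batch of canonical SMILES.
.openbabelBits <- function(canonical, obname, nbits) {
    named <- stats::setNames(canonical, sprintf("g%d", seq_along(canonical)))
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(named))
    fp <- ChemmineR::fingerprintOB(sdf, obname)
    m <- fp@fpma
    lapply(seq_len(nrow(m)), function(i)
        as.integer(which(m[i, ] != 0) - 1L))
}

#' Convert SMILES to molecular fingerprints
#'
#' SMILES are canonicalized first, so equivalent notations of the same
#' molecule always yield identical fingerprints, and the result is
#' deterministic for a fixed (SMILES, scheme) pair.
#'
#' @param x character vector of SMILES strings.
#' @param scheme a [fingerprintScheme()].
#' @return a single [Fingerprint-class] when `length(x) == 1`, otherwise a
#'   named list of fingerprints.
#' @examples
#' fp <- smilesToFingerprint("CCO")
#' identical(fp@bits, smilesToFingerprint("OCC")@bits)
#' @export
smilesToFingerprint <- function(x, scheme = fingerprintScheme()) {
    stopifnot(inherits(scheme, "FingerprintScheme"))
    can <- canonicalizeSmiles(x)
    if (anyNA(can))
        .stopf("unparseable SMILES: %s",
               paste(x[is.na(can)], collapse = ", "))
    bitsets <- if (scheme$type == "circular") {
        graphs <- .smilesGraphs(can)
        lapply(graphs, .circularBits, radius = scheme$radius,
               nbits = scheme$bits)
    } else {
        obname <- c(fp2 = "FP2", maccs = "MACCS")[[scheme$type]]
        .openbabelBits(can, obname, scheme$bits)
    }
    fps <- lapply(bitsets, function(b)
        methods::new("Fingerprint", bits = b, nbits = scheme$bits,
                     scheme = scheme$id))
    if (!is.null(names(x))) names(fps) <- names(x)
    if (length(fps) == 1L) fps[[1L]] else fps
}

#' Tanimoto dissimilarity between two fingerprints
#'
#' Returns `1 - |A intersect B| / |A union B|` on the set-bit positions. Two
#' feature-free (all-zero) fingerprints are defined to have dissimilarity 0:
#' their representations are identical.
#'
#' @param a,b [Fingerprint-class] objects with matching `nbits` and scheme.
#' @return a number in `[0, 1]`.
#' @examples
#' f1 <- smilesToFingerprint("CCO")
#' f2 <- smilesToFingerprint("CCCO")
#' tanimotoDissimilarity(f1, f2)
#' @export
tanimotoDissimilarity <- function(a, b) {
    stopifnot(is(a, "Fingerprint"), is(b, "Fingerprint"))
    if (a@nbits != b@nbits || a@scheme != b@scheme)
        .stopf("incompatible fingerprints: %s/%d vs %s/%d",
               a@scheme, a@nbits, b@scheme, b@nbits)
    u <- length(union(a@bits, b@bits))
    if (u == 0L) return(0)
    1 - length(intersect(a@bits, b@bits)) / u
}

#' Pairwise Tanimoto dissimilarity matrix
#'
#' Computes the symmetric metabolite-by-metabolite Tanimoto dissimilarity
#' matrix over all valid records. For a [MetaboSet-class], records flagged
#' `valid = FALSE` are excluded.
#'
#' @param x a [MetaboSet-class] or a (optionally named) character vector of
#'   SMILES.
#' @param scheme a [fingerprintScheme()].
#' @return numeric matrix with zero diagonal, entries in `[0, 1]`, and
#'   metabolite names as dimnames.
#' @examples
#' d <- dissimilarityMatrix(c(a = "CCO", b = "CCCO", c = "c1ccccc1"))
#' @export
setGeneric("dissimilarityMatrix",
    function(x, scheme = fingerprintScheme()) standardGeneric("dissimilarityMatrix"))

#' @rdname dissimilarityMatrix
#' @export
setMethod("dissimilarityMatrix", "character", function(x, scheme) {
    if (length(x) < 3L)
        .stopf("need at least 3 valid metabolites, got %d", length(x))
    if (is.null(names(x))) names(x) <- paste0("met_", seq_along(x))
    fps <- smilesToFingerprint(x, scheme)
    .tanimotoMatrix(fps)
})

#' @rdname dissimilarityMatrix
#' @export
setMethod("dissimilarityMatrix", "MetaboSet", function(x, scheme) {
    keep <- validMetabolites(x)
    if (length(keep) < 3L)
        .stopf("need at least 3 valid metabolites, got %d", length(keep))
    dissimilarityMatrix(smiles(x)[keep], scheme)
})

.tanimotoMatrix <- function(fps) {
    n <- length(fps)
    nbits <- fps[[1L]]@nbits
    M <- matrix(0, n, nbits)
    for (i in seq_len(n)) M[i, fps[[i]]@bits + 1L] <- 1
    inter <- M %*% t(M)
    card <- rowSums(M)
    uni <- outer(card, card, "+") - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 0
    diag(d) <- 0
    dimnames(d) <- list(names(fps), names(fps))
    d
}

#' Fingerprint bit matrix
#'
#' Dense 0/1 matrix of fingerprints (metabolite x bit), suitable for CSV
#' export.
#'
#' @param x a [MetaboSet-class] (valid records only) or character SMILES.
#' @inheritParams dissimilarityMatrix
#' @return integer matrix, one row per metabolite, `scheme$bits` columns.
#' @export
fingerprintMatrix <- function(x, scheme = fingerprintScheme()) {
    sm <- if (is(x, "MetaboSet")) smiles(x)[validMetabolites(x)] else x
    if (is.null(names(sm))) names(sm) <- paste0("met_", seq_along(sm))
    fps <- smilesToFingerprint(sm, scheme)
    if (is(fps, "Fingerprint")) fps <- stats::setNames(list(fps), names(sm)[1L])
    m <- matrix(0L, length(fps), scheme$bits,
                dimnames = list(names(fps), paste0("bit_", seq_len(scheme$bits) - 1L)))
    for (i in seq_along(fps)) m[i, fps[[i]]@bits + 1L] <- 1L
    m
}
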