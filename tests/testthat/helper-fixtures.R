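# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A small three-family panel of homologous-series SMILES with family truth.
familyPanel <- function(nPerFamily = 8L) {
    gen <- generateStructuralPanel(nPerFamily = nPerFamily, seed = 1L)
    sm <- setNames(gen$panel$smiles, gen$panel$name)
    list(smiles = sm, family = unname(gen$truth$family[names(sm)]),
         panel = gen$panel, truth = gen$truth)
}

# Random sparse fingerprint for oracle tests.
randomFingerprint <- function(nbits = 128L, scheme = "test/128") {
    nset <- sample.int(nbits %/% 2L, 1L)
    bits <- sort(sample.int(nbits, nset)) - 1L
    new("Fingerprint", bits = as.integer(bits), nbits = as.integer(nbits),
        scheme = scheme)
}

# Independent brute-force silhouette: plain double loops over points and
# clusters, no shared code with the implementation.
bruteSilhouette <- function(coords, labels) {
    D <- as.matrix(dist(coords))
    labs <- unique(labels)
    s <- numeric(length(labels))
    for (i in seq_along(labels)) {
        own <- setdiff(which(labels == labels[i]), i)
        if (!length(own)) { s[i] <- 0; next }
        a <- mean(D[i, own])
        b <- Inf
        for (g in setdiff(labs, labels[i]))
            b <- min(b, mean(D[i, labels == g]))
        s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    mean(s)
}

# Independent branch enumerator: recursive leaf-set collection on the
# hclust merge matrix.
bruteBranchCount <- function(hc, minSize) {
    leaves <- function(node) {
        if (node < 0) return(hc$labels[-node])
        c(leaves(hc$merge[node, 1]), leaves(hc$merge[node, 2]))
    }
    sum(vapply(seq_len(nrow(hc$merge)),
               function(i) length(leaves(i)) >= minSize, logical(1)))
}

# Panel of bare records for concentration-level simulations (no chemistry).
plainPanel <- function(n) {
    data.frame(name = sprintf("met_%03d", seq_len(n)),
               smiles = rep("C", n),
               hmdb_id = rep("", n))
}

# Truth with nModules disjoint modules of mSize members each.
plainTruth <- function(n, nModules, mSize, effects = 0, latentSd = 1) {
    stopifnot(nModules * mSize <= n)
    nm <- sprintf("met_%03d", seq_len(n))
    modules <- split(nm[seq_len(nModules * mSize)],
                     rep(seq_len(nModules), each = mSize))
    names(modules) <- as.character(seq_len(nModules))
    list(modules = modules,
         effects = setNames(rep_len(effects, nModules), names(modules)),
         latentSd = setNames(rep_len(latentSd, nModules), names(modules)))
}

writeTempPanel <- function(mset, dir = withr::local_tempdir(.local_envir = parent.frame())) {
    writePanel(mset, file.path(dir, "panel.csv"),
               file.path(dir, "concentrations.csv"))
    dir
}
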