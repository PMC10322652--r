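test_that("branch enumeration matches exhaustive traversal on known trees", {
    # n = 8: every internal node has >= 2 leaves, so minSize 2 keeps all 7
    hc <- hclust(dist(c(1, 2, 10, 11, 100, 101, 1000, 1001)), "average")
    hc$labels <- paste0("L", 1:8)
    expect_length(allBranches(hc, minSize = 2), 7)
    # caterpillar over 5 leaves: branch sizes 2,3,4,5 -> three of size >= 3
    cat5 <- hclust(dist(c(0, 1, 3, 7, 15)), "single")
    cat5$labels <- paste0("L", 1:5)
    ms <- allBranches(cat5, minSize = 3)
    expect_length(ms, 3)
    expect_setequal(lengths(moduleMembers(ms)), c(3, 4, 5))
})

test_that("branch counts equal the brute-force oracle on random trees", {
    withr::local_seed(31)
    for (rep in seq_len(50)) {
        n <- sample(4:20, 1)
        hc <- hclust(dist(matrix(rnorm(n * 2), n)),
                     sample(c("average", "complete", "single", "ward.D2"), 1))
        hc$labels <- paste0("L", seq_len(n))
        minSize <- sample(2:4, 1)
        expect_length(allBranches(hc, minSize),
                      bruteBranchCount(hc, minSize))
    }
})

test_that("module numbering is a stable depth-first order from the root", {
    hc <- hclust(dist(c(1, 2, 10, 11, 100, 101, 1000, 1001)), "average")
    hc$labels <- paste0("L", 1:8)
    ms <- allBranches(hc, minSize = 2)
    expect_identical(names(moduleMembers(ms)), as.character(1:7))
    expect_length(moduleMembers(ms)[["1"]], 8)  # root first
    ms2 <- allBranches(hc, minSize = 2)
    expect_identical(moduleMembers(ms), moduleMembers(ms2))
})

test_that("minSize edge cases behave as specified", {
    hc <- hclust(dist(1:5), "average")
    hc$labels <- paste0("L", 1:5)
    expect_error(allBranches(hc, minSize = 1), "minSize")
    expect_warning(ms <- allBranches(hc, minSize = 6), "exceeds")
    expect_length(ms, 0)
})

test_that("eigen-metabolite matches an independent eigendecomposition", {
    withr::local_seed(17)
    for (rep in seq_len(20)) {
        n <- 30
        pan <- plainPanel(n)
        conc <- matrix(rlnorm(12 * n), 12, n,
                       dimnames = list(NULL, pan$name))
        mset <- MetaboSet(pan, conc, group = rep(c("A", "B"), each = 6),
                          validate = FALSE)
        members <- sample(pan$name, sample(3:6, 1))
        em <- eigenMetabolite(mset, members)
        # oracle: eigendecomposition of the member cross-product matrix,
        # on the same log scale as the default analysis
        Z <- scale(log(t(concentrations(mset)[members, ])))
        ee <- eigen(crossprod(Z), symmetric = TRUE)
        sc <- drop(Z %*% ee$vectors[, 1])
        if (mean(cor(sc, Z)) < 0) sc <- -sc
        expect_equal(unname(em$scores), unname(sc), tolerance = 1e-8)
        expect_equal(em$varianceExplained,
                     ee$values[1] / sum(ee$values), tolerance = 1e-8)
        expect_lt(abs(mean(em$scores)), 1e-10)
        expect_gte(em$memberCorrelation, 0)
    }
})

test_that("a rank-1 module explains all variance", {
    pan <- plainPanel(2)
    base <- rlnorm(10)
    conc <- cbind(met_001 = base, met_002 = 2 * base)
    mset <- MetaboSet(pan, conc, group = rep(c("A", "B"), 5),
                      validate = FALSE)
    em <- eigenMetabolite(mset, pan$name)
    expect_equal(em$varianceExplained, 1.0, tolerance = 1e-12)
    expect_equal(abs(cor(em$scores, log(base))), 1, tolerance = 1e-12)
})

test_that("planted latent patterns are recovered by the eigen-metabolite", {
    withr::local_seed(23)
    cors <- replicate(100, {
        z <- rnorm(24)
        conc <- exp(outer(z, rep(1, 5)) + matrix(rnorm(24 * 5, sd = 0.3), 24))
        colnames(conc) <- sprintf("met_%03d", 1:5)
        mset <- MetaboSet(plainPanel(5), conc, group = rep(c("A", "B"), 12),
                          validate = FALSE)
        em <- eigenMetabolite(mset, sprintf("met_%03d", 1:5))
        cor(em$scores, z)
    })
    expect_gte(median(cors), 0.9)
    expect_true(all(cors > 0))  # sign convention follows the members
})

test_that("eigen-metabolite is scale-invariant and drops constant members", {
    withr::local_seed(3)
    pan <- plainPanel(4)
    conc <- matrix(rlnorm(40), 10, 4, dimnames = list(NULL, pan$name))
    mset <- MetaboSet(pan, conc, group = rep("g", 10), validate = FALSE)
    em1 <- eigenMetabolite(mset, pan$name[1:3])
    conc2 <- conc; conc2[, 2] <- conc2[, 2] * 10
    mset2 <- MetaboSet(pan, conc2, group = rep("g", 10), validate = FALSE)
    em2 <- eigenMetabolite(mset2, pan$name[1:3])
    expect_equal(em1$scores, em2$scores, tolerance = 1e-8)
    # constant member is dropped with a warning; pair degenerates to error
    conc3 <- conc; conc3[, 4] <- 7
    mset3 <- MetaboSet(pan, conc3, group = rep("g", 10), validate = FALSE)
    expect_warning(eigenMetabolite(mset3, pan$name), "constant")
    expect_error(suppressWarnings(
        eigenMetabolite(mset3, pan$name[3:4])), "degenerate")
})

test_that("adding pure-noise members does not increase variance explained", {
    withr::local_seed(29)
    diffs <- replicate(20, {
        z <- rnorm(24)
        conc <- exp(cbind(outer(z, rep(1, 5)) + matrix(rnorm(120, sd = 0.3), 24),
                          matrix(rnorm(120, sd = 1), 24)))
        colnames(conc) <- sprintf("met_%03d", 1:10)
        mset <- MetaboSet(plainPanel(10), conc, group = rep("g", 24),
                          validate = FALSE)
        core <- eigenMetabolite(mset, sprintf("met_%03d", 1:5))
        aug <- eigenMetabolite(mset, sprintf("met_%03d", 1:10))
        aug$varianceExplained - core$varianceExplained
    })
    expect_lte(median(diffs), 0)
})

test_that("module summaries are computed independently and equivariantly", {
    withr::local_seed(41)
    gen <- generateStructuralPanel(4, seed = 1)
    mset <- generateConcentrations(gen$panel, gen$truth, seed = 2)
    hc <- hclust(dist(1:8), "average")
    hc$labels <- metaboliteNames(mset)[1:8]
    ms <- allBranches(hc, minSize = 2)
    em <- wmcsaSummarize(mset, ms)
    expect_identical(nrow(eigenScores(em)), 7L)   # one row per module
    # nested modules both present, no orthogonalization
    expect_true(all(c("1", "2") %in% rownames(eigenScores(em))))
    # permuting samples permutes every score row identically
    perm <- sample(ncol(mset))
    em2 <- wmcsaSummarize(mset[, perm], ms)
    expect_equal(unname(eigenScores(em2)), unname(eigenScores(em)[, perm]),
                 tolerance = 1e-8)
})

test_that("group differences are detected and calibrated by rank testing", {
    withr::local_seed(53)
    # planted 2-noise-SD shift on a structure-only module: detected
    truth <- plainTruth(25, nModules = 5, mSize = 5,
                        effects = c(2, 0, 0, 0, 0), latentSd = 0)
    hits <- replicate(50, {
        mset <- generateConcentrations(plainPanel(25), truth,
                                       seed = sample.int(1e6, 1))
        em <- wmcsaSummarize(mset, truth$modules)
        dt <- differentialModules(em, sampleGroups(mset), c("WT", "MYC"))
        dt$p_adj[dt$module_id == "1"] < 0.05
    })
    expect_gte(mean(hits), 0.8)
    # identical scores in both groups: p = 1 under mid-rank handling
    E <- matrix(rep(c(1, 2, 3), 8), nrow = 2, byrow = TRUE,
                dimnames = list(c("1", "2"), NULL))
    dt <- differentialModules(E, rep(c("A", "B"), each = 6))
    expect_equal(dt$p, c(1, 1))
    expect_identical(dt$direction, c(0, 0))
})

test_that("contrast preconditions are enforced", {
    E <- matrix(rnorm(12), 1, 12, dimnames = list("1", NULL))
    expect_error(differentialModules(E, rep(c("A", "B"), each = 6),
                                     c("A", "C")), "not present")
    expect_error(differentialModules(E, c(rep("A", 10), "B", "B"),
                                     c("A", "B")), "at least 3")
})
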