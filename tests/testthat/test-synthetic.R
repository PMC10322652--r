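test_that("generated panels are valid, deterministic and family-coherent", {
    gen <- generateStructuralPanel(8, seed = 1)
    expect_identical(nrow(gen$panel), 24L)
    expect_false(anyNA(canonicalizeSmiles(gen$panel$smiles)))
    gen2 <- generateStructuralPanel(8, seed = 1)
    expect_identical(gen$panel, gen2$panel)
    expect_error(generateStructuralPanel(8, families = c("fattyAcid", "xyz")),
                 "unknown family")
    expect_error(generateStructuralPanel(2), "nPerFamily")
})

test_that("within-family similarity exceeds between-family for every family", {
    # the panel series are deterministic; check across generator seeds anyway
    for (seed in 1:10) {
        gen <- generateStructuralPanel(6, seed = seed)
        D <- dissimilarityMatrix(setNames(gen$panel$smiles, gen$panel$name))
        fam <- unname(gen$truth$family[rownames(D)])
        for (g in unique(fam)) {
            simWithin <- mean(1 - D[fam == g, fam == g][upper.tri(diag(sum(fam == g)))])
            simBetween <- mean(1 - D[fam == g, fam != g])
            expect_gt(simWithin, simBetween)
        }
    }
})

test_that("all four family specs produce parseable homologous series", {
    gen <- generateStructuralPanel(
        4, families = c("fattyAcid", "aminoAcid", "imidazole", "sugarAlcohol"),
        seed = 1)
    expect_identical(nrow(gen$panel), 16L)
    expect_false(anyNA(canonicalizeSmiles(gen$panel$smiles)))
})

test_that("concentrations are reproducible, positive and panel-shaped", {
    gen <- generateStructuralPanel(4, seed = 1)
    m1 <- generateConcentrations(gen$panel, gen$truth, seed = 3)
    m2 <- generateConcentrations(gen$panel, gen$truth, seed = 3)
    expect_equal(concentrations(m1), concentrations(m2))
    expect_true(all(concentrations(m1) > 0))
    expect_identical(dim(m1), c(12L, 12L))
    expect_identical(levels(sampleGroups(m1)), c("WT", "MYC"))
    m3 <- generateConcentrations(gen$panel, gen$truth, seed = 4)
    expect_false(identical(concentrations(m1), concentrations(m3)))
    expect_error(generateConcentrations(gen$panel, gen$truth, noiseSd = 0),
                 "noiseSd")
})

test_that("a zero planted effect leaves group means at the null", {
    truth <- plainTruth(10, nModules = 2, mSize = 5, effects = 0)
    ps <- vapply(1:200, function(i) {
        mset <- generateConcentrations(plainPanel(10), truth, seed = i)
        lc <- log(concentrations(mset)["met_001", ])
        g <- sampleGroups(mset)
        t.test(lc[g == "WT"], lc[g == "MYC"])$p.value
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("planted modules carry the requested covariance", {
    withr::local_seed(71)
    truth <- plainTruth(20, nModules = 2, mSize = 5, latentSd = c(1, 0))
    mset <- generateConcentrations(plainPanel(20), truth, nPerGroup = 50,
                                   noiseSd = 0.3, seed = 9)
    lc <- t(log(concentrations(mset)))
    corLatent <- mean(cor(lc[, truth$modules[["1"]]])[upper.tri(diag(5))])
    corFlat <- mean(cor(lc[, truth$modules[["2"]]])[upper.tri(diag(5))])
    expect_gt(corLatent, 0.8)            # 1 / (1 + 0.09) ~ 0.92 expected
    expect_lt(abs(corFlat), 0.3)
})

test_that("fixture directories are complete and self-consistent", {
    dir <- withr::local_tempdir()
    fx <- writeFixtures(dir, nPerFamily = 3, nCards = 4, seed = 2)
    expect_true(all(file.exists(file.path(dir,
        c("panel.csv", "concentrations.csv", "truth.json")))))
    expect_length(list.files(file.path(dir, "metabocards"), "\\.xml$"), 4)
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    expect_identical(sort(unname(unlist(truth$modules))),
                     sort(fx$panel$name))
    cards <- readMetabocards(file.path(dir, "metabocards"))
    expect_length(cards, 4)
    mset <- readPanel(file.path(dir, "panel.csv"),
                      file.path(dir, "concentrations.csv"))
    expect_identical(metaboliteNames(mset), fx$panel$name)
})
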