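test_that("panel and concentration files round-trip field-for-field", {
    gen <- generateStructuralPanel(nPerFamily = 3, seed = 1)
    mset <- generateConcentrations(gen$panel, gen$truth, nPerGroup = 6,
                                   seed = 1)
    dir <- writeTempPanel(mset)
    back <- readPanel(file.path(dir, "panel.csv"),
                      file.path(dir, "concentrations.csv"))
    expect_identical(metaboliteNames(back), metaboliteNames(mset))
    expect_identical(unname(smiles(back)), unname(smiles(mset)))
    expect_identical(unname(hmdbId(back)), unname(hmdbId(mset)))
    expect_identical(as.character(sampleGroups(back)),
                     as.character(sampleGroups(mset)))
    expect_equal(concentrations(back), concentrations(mset),
                 tolerance = 1e-12)
    expect_equal(dim(back), c(nrow(gen$panel), 12L))
})

test_that("unparseable SMILES are flagged, retained, and excluded downstream", {
    pan <- data.frame(name = c("ok1", "bad", "ok2", "ok3"),
                      smiles = c("CCO", "not_a_smiles", "CCCO", "CCCCO"),
                      hmdb_id = "")
    conc <- matrix(rlnorm(24), 6, 4, dimnames = list(NULL, pan$name))
    expect_message(mset <- MetaboSet(pan, conc, group = rep("A", 6)),
                   "1 metabolite\\(s\\) excluded")
    expect_identical(metaboliteNames(mset), pan$name)       # retained
    expect_identical(validMetabolites(mset), c("ok1", "ok2", "ok3"))
    d <- dissimilarityMatrix(mset)
    expect_false("bad" %in% rownames(d))                    # excluded
})

test_that("extra concentration columns are dropped by name intersection", {
    gen <- generateStructuralPanel(nPerFamily = 3, seed = 1)
    mset <- generateConcentrations(gen$panel, gen$truth, seed = 1)
    dir <- writeTempPanel(mset)
    conc <- read.csv(file.path(dir, "concentrations.csv"),
                     check.names = FALSE)
    conc$phantom_metabolite <- 1
    write.csv(conc, file.path(dir, "concentrations.csv"), row.names = FALSE)
    expect_warning(
        back <- readPanel(file.path(dir, "panel.csv"),
                          file.path(dir, "concentrations.csv")),
        "phantom_metabolite")
    # set-intersection oracle on the column names
    expected <- intersect(gen$panel$name,
                          setdiff(colnames(conc), c("sample_id", "group")))
    expect_identical(metaboliteNames(back), expected)
})

test_that("format errors name the missing column; zero overlap errors", {
    dir <- withr::local_tempdir()
    write.csv(data.frame(name = "a", smiles = "C"),
              file.path(dir, "panel.csv"), row.names = FALSE)
    write.csv(data.frame(sample_id = "s1", group = "A", a = 1),
              file.path(dir, "conc.csv"), row.names = FALSE)
    expect_error(readPanel(file.path(dir, "panel.csv"),
                           file.path(dir, "conc.csv")), "hmdb_id")
    write.csv(data.frame(name = "a", smiles = "C", hmdb_id = ""),
              file.path(dir, "panel.csv"), row.names = FALSE)
    write.csv(data.frame(sample_id = "s1", a = 1),
              file.path(dir, "conc.csv"), row.names = FALSE)
    expect_error(readPanel(file.path(dir, "panel.csv"),
                           file.path(dir, "conc.csv")), "group")
    write.csv(data.frame(sample_id = "s1", group = "A", other = 1),
              file.path(dir, "conc.csv"), row.names = FALSE)
    expect_error(suppressWarnings(
        readPanel(file.path(dir, "panel.csv"), file.path(dir, "conc.csv"))),
        "no overlap")
})

test_that("duplicate metabolite names are an error, not a merge", {
    pan <- data.frame(name = c("a", "a", "b"),
                      smiles = c("C", "CC", "CCC"), hmdb_id = "")
    conc <- matrix(1, 3, 3, dimnames = list(NULL, c("a", "a", "b")))
    expect_error(MetaboSet(pan, conc, group = rep("g", 3)), "duplicate")
})

test_that("imputation fills per-metabolite minima or medians, none errors", {
    pan <- plainPanel(2)
    conc <- matrix(c(4, 2, NA, 8, 1, 3, 5, NA), 4, 2,
                   dimnames = list(NULL, pan$name))
    mset <- MetaboSet(pan, conc, group = rep(c("A", "B"), 2),
                      validate = FALSE)
    expect_message(imp <- imputeConcentrations(mset, "min"), "imputed 2")
    expect_equal(unname(concentrations(imp)["met_001", 3]), 2)
    imp2 <- suppressMessages(imputeConcentrations(mset, "median"))
    expect_equal(unname(concentrations(imp2)["met_002", 4]), 3)
    expect_error(imputeConcentrations(mset, "none"), "missing")
})
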