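cardDir <- system.file("extdata", "metabocards", package = "MetaboModules")

test_that("a full metabocard is parsed field-for-field", {
    card <- readMetabocard(file.path(cardDir, "synthetic_HMDB0990001.xml"))
    expect_identical(hmdbId(card), "HMDB0990001")
    expect_identical(card@names[1], "Synthocarnosine")
    expect_length(card@names, 3)
    expect_equal(card@averageMass, 146.1451)
    expect_equal(card@monoisotopicMass, 146.0691)
    expect_setequal(card@substituents,
                    c("Imidazolyl carboxylic acid", "Dipeptide"))
    expect_identical(card@pathways, "Histidine metabolism")
    expect_identical(card@diseases, "Synthetic myopathy")
    expect_identical(unname(card@taxonomy["kingdom"]), "Organic compounds")
    expect_true("CNDP1" %in% card@enzymes)
})

test_that("absent blocks give empty fields, never an error", {
    card <- readMetabocard(file.path(cardDir, "synthetic_HMDB0990002.xml"))
    expect_length(card@diseases, 0)
    expect_length(card@pathways, 2)       # corrected monoisotopic spelling
    expect_equal(card@monoisotopicMass, 240.1222)
    minimal <- readMetabocard(file.path(cardDir, "synthetic_HMDB0990003.xml"))
    expect_length(minimal@pathways, 0)
    expect_length(minimal@enzymes, 0)
    expect_true(is.na(minimal@averageMass))
    expect_identical(minimal@substituents, "Carboxylic acid")
})

test_that("the parser is total on the bundled fixture corpus", {
    cards <- readMetabocards(cardDir)
    expect_length(cards, 3)
    expect_identical(sort(names(cards)),
                     c("HMDB0990001", "HMDB0990002", "HMDB0990003"))
})

test_that("malformed input is rejected with a path-bearing message", {
    bad <- withr::local_tempfile(fileext = ".xml")
    writeLines("<metabolite><accession>HMDB1</unclosed>", bad)
    expect_error(readMetabocard(bad), "malformed")
    wrongRoot <- withr::local_tempfile(fileext = ".xml")
    writeLines("<compound><accession>HMDB1</accession></compound>", wrongRoot)
    expect_error(readMetabocard(wrongRoot), "expected <metabolite>")
})

test_that("attribute tables are assembled per kind with defined collisions", {
    cards <- readMetabocards(cardDir)
    tab <- extractAttributes(cards, "substituent")
    expect_length(tab, 3)
    expect_identical(attr(tab, "kind"), "substituent")
    tax <- extractAttributes(cards, "taxonomy")
    expect_true("kingdom:Organic compounds" %in% tax[["HMDB0990001"]])
    expect_true("sub_class:Fatty acids and conjugates" %in%
                tax[["HMDB0990003"]])
    expect_error(extractAttributes(cards, "flavor"), "unknown attribute kind")
    # duplicate accession: last card wins, with a warning
    dup <- c(cards, cards["HMDB0990001"])
    expect_warning(tab2 <- extractAttributes(dup, "substituent"),
                   "duplicate")
    expect_length(tab2, 3)
})

test_that("panel keying restricts and renames the attribute table", {
    cards <- readMetabocards(cardDir)
    pan <- data.frame(name = c("carn", "ans", "other"),
                      smiles = c("C", "CC", "CCC"),
                      hmdb_id = c("HMDB0990001", "HMDB0990002", ""))
    conc <- matrix(1:12, 4, 3, dimnames = list(NULL, pan$name))
    mset <- MetaboSet(pan, conc, group = rep("g", 4), validate = FALSE)
    tab <- extractAttributes(cards, "pathway", panel = mset)
    expect_identical(sort(names(tab)), c("ans", "carn"))
    expect_identical(tab[["carn"]], "Histidine metabolism")
})

test_that("perfect overlap gives the hypergeometric closed form", {
    universe <- sprintf("m%02d", 1:20)
    tab <- structure(setNames(
        c(rep(list("X"), 4), rep(list(character(0)), 16)), universe),
        kind = "substituent")
    mods <- list("1" = universe[1:4])
    res <- featureEnrichment(mods, tab, universe)
    expect_equal(res$p[res$value == "X"], 1 / choose(20, 4),
                 tolerance = 1e-12)
    expect_identical(c(res$a, res$b, res$c, res$d), c(4L, 0L, 0L, 16L))
})

test_that("enrichment p-values match a hypergeometric summation oracle", {
    withr::local_seed(61)
    for (rep in seq_len(100)) {
        N <- sample(8:30, 1)
        nIn <- sample(2:(N - 2), 1)
        K <- sample(2:(N - 1), 1)
        universe <- sprintf("m%03d", seq_len(N))
        carriers <- sample(universe, K)
        inMod <- sample(universe, nIn)
        tab <- structure(setNames(lapply(universe, function(m)
            if (m %in% carriers) "X" else character(0)), universe),
            kind = "substituent")
        res <- featureEnrichment(list("1" = inMod), tab, universe)
        a <- length(intersect(inMod, carriers))
        # oracle: explicit summation over the hypergeometric tail
        pOracle <- sum(vapply(a:min(nIn, K), function(k)
            choose(K, k) * choose(N - K, nIn - k) / choose(N, nIn),
            numeric(1)))
        expect_equal(res$p, pOracle, tolerance = 1e-10)
    }
})

test_that("a universally carried attribute is uninformative", {
    universe <- sprintf("m%02d", 1:10)
    tab <- structure(setNames(rep(list("X"), 10), universe),
                     kind = "substituent")
    res <- featureEnrichment(list("1" = universe[1:4]), tab, universe)
    expect_equal(res$p, 1)
    # 0/0 odds ratio: reported as 1 (the attribute does not discriminate)
    expect_identical(res$odds_ratio, 1)
})

test_that("enrichment is invariant to module numbering and BH is monotone", {
    cards <- readMetabocards(cardDir)
    universe <- names(cards)
    tab <- extractAttributes(cards, "substituent")
    mods <- list("1" = universe[1:2], "2" = universe[2:3])
    r1 <- featureEnrichment(mods, tab, universe)
    r2 <- featureEnrichment(rev(mods), tab, universe)
    for (v in unique(r1$value))
        expect_equal(sort(r1$p[r1$value == v]), sort(r2$p[r2$value == v]))
    ord <- order(r1$p)
    expect_true(all(diff(r1$p_adj[ord]) >= -1e-12))
    expect_true(all(r1$p_adj >= r1$p - 1e-12))
})
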