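Package: MetaboModules
Title: Structural Clustering and Module Analysis of Metabolite Panels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters metabolites by chemical-structure similarity and
    summarizes the resulting structural modules against sample
    concentrations. SMILES strings are converted to molecular
    fingerprints, pairwise Tanimoto dissimilarities are embedded by
    classical multidimensional scaling and sharpened by an
    accuracy-maximization (KODAMA-style) procedure, and chemical classes
    are identified by silhouette-selected hierarchical clustering with
    repeat-averaged consensus labels. Within a class, every dendrogram
    branch defines a candidate module that is summarized by its
    eigen-metabolite (first principal component of member concentration
    profiles), tested for group differences, and annotated by enrichment
    of HMDB metabocard attributes (substituents, taxonomy, enzymes,
    diseases, pathways). Includes a synthetic-data generator for
    structurally distinct SMILES families with planted module covariance
    and group effects, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ChemmineR,
    ChemmineOB,
    xml2,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    withr
biocViews: Metabolomics, Clustering, Cheminformatics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
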