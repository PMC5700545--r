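Package: goMedSel
Title: Gene Ontology Guided Unsupervised Gene Selection and
    Multi-Objective Sample Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unsupervised feature (gene) selection for expression data
    driven by Gene Ontology annotation structure. Genes are represented
    as vectors of structure-based information content (term depth times
    semantic coverage) over enrichment-selected GO terms; partitioning
    around medoids with silhouette-based model selection picks medoid
    genes as the reduced feature set. Samples are then clustered in the
    reduced gene space by an archived multi-objective simulated
    annealer that simultaneously optimises the Xie-Beni, PBM and fuzzy
    c-means objectives and returns the Pareto-archive member with the
    best silhouette. Includes cluster validity indices, synthetic data
    generators with planted structure, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
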