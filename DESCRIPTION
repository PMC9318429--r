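Package: paar
Title: Principal Amalgamation Analysis for Compositional Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomy-guided dimension reduction of compositional (relative
    abundance) microbiome data by principal amalgamation analysis. Taxa are
    greedily amalgamated pairwise into a small number of principal
    compositions while minimizing the loss of a chosen diversity measure:
    Simpson's diversity index, the Shannon-Wiener index, Bray-Curtis
    dissimilarity, or the weighted UniFrac distance. Amalgamation can be
    unconstrained or confined to the taxonomic hierarchy (weak or strong
    guidance), and the full merge path is returned so the data can be cut at
    any number of principal compositions. Includes readers for abundance
    tables, lineage strings and Newick trees, a synthetic-data generator,
    and dendrogram, scree and NMDS ordination graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    ggplot2,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    mclust,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
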