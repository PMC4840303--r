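Package: SyntrophNet
Title: Co-Occurrence Networks, Diversity, and Methanogenic Stoichiometry
    for Anaerobic Enrichment Cultures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for small sets of related methanogenic
    enrichment cultures profiled by 16S rRNA amplicon sequencing.
    Provides OTU-table input/output built on SummarizedExperiment,
    alpha diversity (Shannon, finite-sample Simpson dominance,
    bias-corrected Chao1, hypergeometric rarefaction), Bray-Curtis
    beta diversity with UPGMA sample clustering, co-occurrence network
    inference by prevalence/abundance filtering and thresholded Pearson
    correlation with connected-component decomposition, generalized
    Buswell-Boyle stoichiometry for theoretical methane yield and
    percent-conversion accounting with reductant-ceiling attribution,
    pairwise global alignment identity for marker-gene fragments, and a
    seeded synthetic community generator with planted co-varying OTU
    blocks for network-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
biocViews: Microbiome, Metagenomics, Network, Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SyntrophNet-package.R'
    'otu-table-io.R'
    'cooccurrence.R'
    'diversity.R'
    'marker-identity.R'
    'stoichiometry.R'
    'pipeline.R'
    'simulate.R'
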