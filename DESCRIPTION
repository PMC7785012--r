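Package: viropop
Title: Viral Population Identification, Clustering and Ecology for
    Stratified Water-Column Viromes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for population-level viromics of
    stratified (oxic/redoxcline/euxinic) water columns: integration of
    multiple virus-detection evidence sources into confidence tiers,
    average-nucleotide-identity clustering of contigs into species-level
    viral populations with longest-member representatives, read-recruitment
    abundance estimation under identity/read-fraction/breadth retention
    rules, community ecology (evenness, second-order jackknife richness,
    accumulation curves, Bray-Curtis dissimilarity, sample dendrograms)
    and habitat-exclusivity classification, hypergeometric gene-sharing
    genus networks, and genomic-context adjudication of putative auxiliary
    metabolic genes. Includes a ground-truthed synthetic virome generator
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    ape,
    igraph,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
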