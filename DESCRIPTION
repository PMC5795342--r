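Package: fernbone
Title: Desk-Scale Phylogenomic Backbone Pipeline for Fern Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, desk-scale re-implementation of a transcriptome-based
    backbone-phylogeny workflow: Markov clustering of an all-vs-all similarity
    graph into homolog families, tree-based paralog pruning to 1-to-1
    orthologs with occupancy and length filters, coalescent (maximum quartet
    support) and concatenation (maximum likelihood) species-tree estimation
    on nucleotide and amino-acid data, a method-by-datatype topology
    comparison report, and Mk-model ancestral-state reconstruction of
    sporangial-annulus characters averaged over a tree sample. A synthetic
    data generator (Yule species trees, multispecies-coalescent gene trees,
    gene duplication and loss, sequence and discrete-character evolution,
    noisy similarity graphs) replaces the raw RNA-seq stages and provides
    ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
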