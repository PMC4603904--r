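Package: AnchorCoal
Title: Anchored-Enrichment Assembly and Coalescent Species-Tree Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline from anchored hybrid-enrichment paired
    reads to a multispecies-coalescent species tree. Implements
    probabilistic read-pair merging, spaced 20-mer reference mapping with
    60-mer de novo extension, binomial-model IUPAC consensus calling with
    coverage soft-masking, shared-20-mer orthology clustering under a
    one-sequence-per-species constraint, three-step alignment masking,
    STAR (coalescence-rank) and MP-EST (triplet pseudo-likelihood)
    species-tree estimation, rooted Robinson-Foulds comparison, and a
    locus-subsampling experiment that measures how many loci each
    species-tree method needs. A coalescent simulator generates species
    trees, gene trees, sequences and paired reads with truth tables for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
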