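Package: sigdecipher
Title: Deciphering Mutational Signatures from Somatic Mutation Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts signatures of mutational processes from catalogs of
    somatic mutations in cancer genomes by nonnegative matrix factorization.
    Models a set of mutational catalogs M as the product of a signature
    matrix P (columns are probability distributions over mutation types)
    and an exposure matrix E (mutations contributed by each process to each
    genome), and recovers P and E through a bootstrap-NMF-consensus
    procedure with multiplicative updates, k-means-style consensus
    clustering of signatures across bootstrap iterations, and silhouette
    based reproducibility assessment. Includes mutation-type alphabets with
    trinucleotide and pentanucleotide context, transcriptional strand
    annotation and extended classes (kataegis, dinucleotides, indels at
    repeats or microhomologies), catalog construction from per-mutation
    tables, a catalog simulator with Poisson noise for power analyses,
    model selection over the number of signatures, and accuracy metrics
    against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
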