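Package: duplicability
Title: Evolutionary Rates of Duplicable and Singleton Genes in Primates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for asking whether genes that duplicate in the great apes
    already evolved faster before they duplicated. Classifies gene family
    trees into singleton and duplicable sets with a patristic-distance rule
    that excludes ancestral duplication followed by loss, estimates pairwise
    dN/dS between macaque and gibbon orthologs under a Goldman-Yang codon
    model with F3x4 frequencies (with a Nei-Gojobori counting oracle),
    fits branch models on gene trees by Felsenstein pruning for
    likelihood-ratio tests of post-duplication asymmetry and acceleration,
    and runs LOWESS-residual randomization tests against expression, CDS
    length, genomic length and GC3 covariates. A synthetic gene-family
    simulator generates primate-like trees, codon alignments and covariates
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
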