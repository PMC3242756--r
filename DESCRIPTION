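Package: epistrat
Title: Subset Strategies and Permutation FDR for Epistasis Detection in
    eQTL Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening pairs of genetic markers for epistatic
    (interaction) effects on gene-expression traits.  Implements marginal
    and two-locus interaction linear-model tests with a vectorized pair
    scan, candidate SNP-pair subset strategies based on marginal
    association (marginal-by-marginal, marginal-by-genomewide) or on a
    protein-interaction network, matched random control strategies, and a
    shared-permutation minimum-p-value false discovery rate estimator
    that exploits the normal quantile transformation of all traits to a
    common distribution.  A synthetic-data generator produces haploid
    cross or diploid Hardy-Weinberg genotypes, phenotypes with planted
    marginal and epistatic effects, SNP-to-gene maps and interaction
    networks with known ground truth, so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
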