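Package: ypopgen
Title: Y-Chromosome STR and Haplogroup Population Genetics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forensic and population-genetic analysis of Y-chromosome STR
    haplotypes and SNP-defined haplogroups. Reads and validates per-male
    Y-STR/Y-SNP haplotype tables (Yfiler Plus style panels, including
    multi-copy loci treated as allelic combinations and the DYS389b
    derivation), parses ISOGG-style haplogroup nomenclature and assigns
    haplogroups from SNP states, and computes the standard forensic summary
    statistics (gene and haplotype diversity, discrimination capacity, match
    probability). Population structure is quantified by AMOVA-based pairwise
    Fst with permutation testing, principal component analysis of haplogroup
    frequency matrices, and inverse-distance-weighted geographic frequency
    surfaces. Weighted median-joining haplotype networks support mixed
    SNP/STR character data. Time to the most recent common ancestor is
    estimated by average-squared-distance and rho statistics and by a
    single-population Bayesian coalescent MCMC under the stepwise mutation
    model. A coalescent simulator with stepwise STR mutation generates
    multi-population synthetic datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
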