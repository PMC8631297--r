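Package: eokochia
Title: Phylogeography and Coalescent Demographic Inference for a Three-Population Narrow Endemic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis pipeline for a narrow endemic plant
    sampled from three isolated coastal populations (Palinuro, Capri,
    Strombolicchio). Provides ddRAD-style SNP filtering on diploid genotype
    matrices read from VCF, diversity and differentiation statistics
    (observed/expected heterozygosity, Fis, Weir-Cockerham Fst, allele-sharing
    and co-ancestry distances), gap-statistic selection of the number of
    genetic clusters with classical MDS and neighbour-joining trees,
    statistical-parsimony (TCS-style) plastid haplotype networks with inferred
    intermediate haplotypes, a backward-in-time coalescent simulator for four
    explicit island-colonization scenarios with founder bottlenecks, and
    approximate Bayesian computation with random forests (LDA-augmented
    scenario choice with per-tree votes and posterior probability, and
    quantile-forest parameter estimation). A synthetic-data generator emulates
    the study design end to end so the whole pipeline runs without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    igraph,
    ranger,
    MASS,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
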