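Package: kisim
Title: Kinship Index Based Selection in Simulated Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of small-population pig
    breeding programs, built to evaluate kinship index based selection (KIS):
    candidates are ranked by the 0/1/2 genotype similarity of their marker
    genotypes to a designed "ideal individual" carrying the beneficial allele
    at every locus linked to the breeding objective.  The package simulates
    founder genomes, additive / dominance / epistatic trait architectures
    calibrated to unit genetic variance, Mendelian inheritance under the
    Haldane crossover model, and a two-breed hybridization program with five
    generations of purebred reproduction.  Comparator selection criteria are
    provided (GBLUP through a VanRaden genomic relationship matrix, BayesB
    marker-effect MCMC, and oracle true-breeding-value selection), together
    with replicated experiments, ANOVA with compact letter displays,
    robustness perturbations of the ideal individual (false-negative locus
    deletion, pseudo-positive loci, negative controls), VCF / dosage-matrix
    I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    optparse,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
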