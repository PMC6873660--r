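Package: speedgs
Title: Stochastic Simulation of Speed Breeding and Genomic Selection in
    Allogamous Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of breeding programs for outcrossing
    (allogamous) crops such as tall fescue. Simulates an allohexaploid base
    population through speciation, hybridization and expansion with linkage
    disequilibrium and heterozygosity diagnostics; samples mixed-architecture
    quantitative trait loci with a Cholesky-rescaling method for correlated
    effects drawn from unequal-variance distributions; runs a multi-stage
    phenotypic selection program and SpeedGS scenarios that combine genomic
    selection with speed-breeding rounds; trains Bayesian ridge regression
    prediction models on pooled plot genotypes; and tracks genetic gain,
    prediction accuracy, VanRaden genomic relationships and inbreeding rates
    over replicated experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
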