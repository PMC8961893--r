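Package: lcpopgen
Title: Population Structure and Stratified GWAS from Low-Coverage Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for microgeographic population-structure and
    stratified association analysis of low-coverage whole-genome genotype
    panels, as used for Amazonian malaria-vector mosquitoes. Provides
    genotype- and site-level quality control for VCF panels carrying
    genotype likelihoods (depth/quality masking, allele-frequency and
    missingness filters, within-stratum Hardy-Weinberg exact tests),
    a frequency-prior EM genotype refiner with a posterior-probability
    acceptance gate, linkage-disequilibrium decay profiling with a
    1/log(distance) model fit and window-based marker pruning,
    identity-by-state and Weir-Cockerham FST with permutation tests and
    Benjamini-Hochberg FDR, PCA and k-means stratification with an
    elbow-based optimal-k rule, the continuity-corrected
    Cochran-Mantel-Haenszel stratified allelic association test with
    gene-adjacency annotation from GFF3, and a Balding-Nichols simulator
    of stratified low-coverage panels with a truth sidecar for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
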