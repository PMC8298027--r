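Package: oysterGS
Title: Genomic Evaluation for Family-Based Oyster Breeding Programs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic evaluation of family-structured aquaculture
    breeding populations, modelled on a two-generation Portuguese oyster
    (Crassostrea angulata) selection program. Provides a synthetic data
    generator (pedigree construction, gene dropping, multi-trait phenotype
    simulation with known variance components), genotype quality control
    (call-rate filtering, mean imputation, VCF conversion), derived shell
    and meat-yield traits, genomic (VanRaden and per-marker standardized)
    and pedigree numerator relationship matrices, average-information REML
    for univariate and bivariate animal models with arbitrary relationship
    matrices, GBLUP/ABLUP mixed-model solutions with allele substitution
    effect back-solving, replicated k-fold cross-validated predictive
    ability, and population-structure statistics (pairwise divergence,
    nucleotide diversity, neighbor-joining trees, fixation index).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
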