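Package: mkgamma
Title: Hierarchical McDonald-Kreitman Inference of Scaled Selection
    Coefficients in Social Insects
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A two-species population-genomics pipeline for quantifying
    adaptive protein evolution: variant filtering, codon-level
    synonymous/non-synonymous effect annotation, per-gene
    McDonald-Kreitman polymorphism/divergence tables, and a hierarchical
    Bayesian Poisson model that maps each gene's selection effect to a
    population-scaled selection coefficient (gamma = 2*Ne*s) through
    Poisson-random-field theory. Includes reciprocal-best-hit orthology,
    caste-biased gene-set statistics (overlap enrichment, proportion
    tests, ANOVA/Tukey on gamma), and a synthetic-data module that
    generates genomes, VCFs, expression tables and similarity-hit tables
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    lme4,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
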