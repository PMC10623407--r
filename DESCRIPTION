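Package: panelgwas
Title: Population Genomics and Non-Additive GWAS for Crop Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for SNP-array-scale population genomics of
    clonally propagated crop diversity panels: genotype quality control and
    clone detection by identity-by-state, ancestry estimation by masked
    matrix factorization, additive kinship, PCA and UPGMA trees, runs of
    homozygosity and genomic inbreeding coefficients, linkage-disequilibrium
    decay, BLUP phenotype modelling with broad-sense heritability, mixed-model
    association scans under additive, dominant, recessive and overdominant
    genotype encodings with kinship and structure corrections, QTL calling
    with variance-explained accounting, and LD-bounded candidate-gene and
    coexpression-network enrichment analysis. Includes a synthetic-data
    generator that plants known population structure, clones, autozygous
    segments and QTL effects for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ape,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
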