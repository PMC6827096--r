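Package: mosaicgp
Title: Multi-Breed Genomic Prediction with Block-Resampled Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for evaluating genomic prediction across
    structured livestock populations. Generates phased multi-breed founder
    genotypes with hierarchical population structure and realistic linkage
    disequilibrium, expands each breed by fixed-length haplotype-block
    resampling so that allele frequencies and within-block LD of the
    founders are preserved, simulates quantitative traits under
    configurable QTL architectures and heritabilities, and evaluates
    GBLUP (genomic best linear unbiased prediction) accuracy under
    single-breed, multi-breed and pooled reference-population designs.
    Includes genotype quality control, PLINK text import/export, PCA and
    K-means breed grouping, and persistence-of-phase LD diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
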