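Package: microbiability
Title: Microbiability Estimation and Multi-Kernel Genomic Prediction from
    Rumen Microbiome and Host Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions quantitative-trait variance (milk fat, protein and
    fatty-acid composition in dairy cattle) into host-genetic and
    rumen-microbiome components using relationship kernels built from SNP
    genotypes (VanRaden genomic relationship matrix) and from standardized
    OTU count tables (microbial relationship matrix M = BB'/c).  Provides
    average-information REML with EM fallback for variance-component
    estimation, heritability and microbiability ratios with delta-method
    standard errors, cross-validated GBLUP/GFBLUP prediction with genomic,
    microbial and genome-by-microbiome interaction kernels, Welch's t model
    comparison with Bonferroni correction, quality-control filters for
    genotype and OTU tables, and a Dirichlet-multinomial synthetic-data
    generator with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    MASS,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
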