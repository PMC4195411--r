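Package: pleioscan
Title: Multi-Trait GWAS with GRAMMAR Residuals, Trait Principal
    Components and Multivariate Bayes Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step mixed-model association analysis for multiple
    correlated quantitative traits in related individuals.  Fits the
    polygenic animal model by restricted maximum likelihood using a
    genomic relationship matrix, scans the model residuals against SNP
    allele doses (the GRAMMAR approach) with permutation-based
    genome-wide significance, condenses traits into principal components
    of the phenotypic correlation matrix for pleiotropy scanning, and
    computes closed-form log10 Bayes factors from a conjugate
    matrix-normal inverse-Wishart multivariate association model.
    Includes marker quality control (minor allele frequency and
    Hardy-Weinberg filters), clumping of significant SNPs into QTL
    regions, PLINK PED/MAP and TSV input/output, and a synthetic-data
    generator emulating the QTL-MAS 2012 workshop dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
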