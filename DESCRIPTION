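Package: pleioscan
Title: Single- and Multi-Trait Mixed-Model GWAS, Meta-Analysis and QTL
    Fine-Mapping on Simulated Livestock Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates genotype/phenotype cohorts that emulate
    deregressed-breeding-value (drEBV) phenotypes of a livestock breeding
    population, and compares three strategies for mapping pleiotropic
    quantitative trait loci (QTL): single-trait linear mixed-model
    association scans (score test with a centred genomic relationship
    matrix), joint multivariate mixed-model scans on complete cases, and
    multi-trait meta-analysis of single-trait summary statistics via the
    t-matrix chi-square statistic. Includes genotype quality control
    (Hardy-Weinberg exact test, call-rate and allele-frequency filters),
    weighted REML genomic heritability, QTL calling in 1-Mb windows with
    lead variants, linkage-disequilibrium neighbourhoods and jointly
    fitted variance explained, genomic-inflation and analytic
    false-discovery-rate diagnostics, and imputation-accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
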