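Package: geneprs
Title: Gene-Based Cross-Ancestry Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of gene-based polygenic risk scores
    (PRS) from two discovery GWAS in different ancestral populations.
    Harmonizes summary statistics to a common effect allele, selects
    cross-population concordant variants (nominally associated in both
    studies with the same direction of effect), partitions them into
    intragenic and intergenic sets under configurable gene-boundary windows,
    derives scoring weights by fixed-effect inverse-variance meta-analysis
    (or imports externally estimated posteriors), scores target-cohort
    imputed dosages, and tests PRS-phenotype association with logistic
    models, family random intercepts, and decile odds-ratio stratification.
    Includes a seeded two-population synthetic GWAS generator
    (Balding-Nichols divergence, copula LD blocks, liability-threshold
    case/control phenotypes) so the whole pipeline can be exercised without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    lme4,
    vcfR,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
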