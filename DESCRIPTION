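Package: gwasfunnel
Title: GWAS and Wrapper-Based Marker Selection for Small Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated genotype-to-risk-model pipeline for small,
    genetically homogeneous case-control cohorts: PLINK-format genotype
    input and quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test in controls, heterozygosity, relatedness),
    covariate-adjusted single-SNP logistic association with genomic-control
    diagnostics (lambda GC, QQ data), association-rule comorbidity mining
    over visit records (support, confidence, lift, chi-square),
    wrapper-based SNP subset selection by best-first forward search scored
    with leave-one-out cross-validation, a fourteen-entry classifier
    registry with repeated stratified cross-validation and stratified
    bootstrap external validation, and cis-eQTL annotation harmonization
    with palindromic-SNP exclusion.  A synthetic-data module generates
    genotype matrices at Hardy-Weinberg equilibrium with optional linkage
    disequilibrium, correlated binary traits with planted additive and
    interaction effects, and visit records with planted lift, so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
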