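Package: episnp
Title: Candidate-Gene SNP-SNP Interaction Scans with Permutation-Based
    Family-Wise Error Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive SNP-by-SNP dosage-interaction logistic regression between
    an index gene and biologically nominated partner genes in case-control data,
    with Wald tests on the interaction coefficient, a case-control
    label-permutation min-p null for family-wise significance, and a replication
    stage. Includes readers and writers for genotype-dosage formats (VCF with DS
    field, a dosage-TSV dialect), sample and gene-region annotation, the standard
    GWAS quality-control filters (missingness, minor allele frequency,
    Hardy-Weinberg exact test in controls, imputation quality), ancestry principal
    components in the Eigenstrat normalization, and a synthetic case-control GWAS
    generator with LD blocks, imputation-dosage noise, site and ancestry
    confounding, and a planted two-locus epistatic effect for end-to-end testing
    without controlled-access genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
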