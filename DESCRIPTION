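Package: fatmap
Title: Window-Based Bayesian GWAS and Deleterious-Variant Association for
    Meat-Type Chicken Carcass Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discovery pipeline for quantitative trait loci (QTL) affecting
    carcass and abdominal-fat traits in meat-type chickens. Implements genotype
    and sequenced-variant quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact testing), Bayesian whole-genome regression (BayesC for
    variance estimation, BayesB for marker effects) with 1-Mb window variance
    decomposition and posterior probability of association, linkage-
    disequilibrium-aware selection of predicted-deleterious SNPs, single-SNP
    linear mixed-model association with additive and genotypic codings and a
    dam-family random effect, and a homozygote-deficit screen for recessive
    lethals. A synthetic-population generator emulating a sire-dam broiler
    reference design provides recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmerTest,
    jsonlite,
    vcfR
Config/testthat/edition: 3
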