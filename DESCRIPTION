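Package: divloss
Title: Windowed Nucleotide Diversity Loss from Multi-Sample VCFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies loss of standing genetic variation between timepoints
    and treatment conditions from multi-sample VCF genotype data. Applies
    per-genotype depth/quality masking and per-site missingness, allele-count
    and indel filters; estimates nucleotide diversity (pi) in fixed genomic
    windows and counts polymorphic SNPs per treatment group; computes
    percent-loss summaries between developmental days and pCO2 conditions;
    and assesses significance with a permutation two-way ANOVA in which
    log-transformed window pi values are shuffled across all windows. Includes
    a synthetic cohort simulator (viability selection plus binomial survival
    drift over replicate larval pools, with pooled-library genotyping
    emulation) so the whole pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
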