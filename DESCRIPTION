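Package: bsascan
Title: Bulked Segregant Analysis by Pooled Sequencing with Block-Wise
    Exact Tests and Sliding-Window Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps recessive loci from bulked segregant analysis sequencing
    (BSA-seq) of backcross or F2 populations. Calls homozygous parent-versus-
    reference SNP markers from per-site base counts, pools consecutive SNPs
    into blocks of a minimum read depth, tests each block's bulk allele
    counts against the cross-design null frequency with exact tests
    (binomial or Fisher), scans the genome with the average -log10(P)
    sliding-window statistic, merges significant windows into candidate
    regions, and narrows regions to runs of SNPs whose bulk reads derive
    exclusively from the mutant parent. Includes a genetic-cross and
    pooled-read simulator with full ground truth, segregation-ratio
    chi-square tests, and fold-coverage arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
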