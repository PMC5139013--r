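Package: aseflow
Title: Allele-Specific Expression Calling and Differential Allelic Imbalance for Heart RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for allele-specific expression (ASE)
    analysis of bulk RNA-seq at heterozygous SNPs. Extracts and counts
    REF/ALT/OTHER bases from uniquely mapped reads, applies a rigorous SNP and
    read filter cascade (coverage minimum, exact Hardy-Weinberg test,
    genotyping rate, mappability, and an exact test against the overall
    genotyping-error rate), calls ASE with an aggregate binomial test or an
    exact conditional negative-binomial test on per-individual allele counts
    with method-of-moments dispersion, controls the false discovery rate by
    Benjamini-Hochberg, quantifies reference-mapping bias by read depth,
    measures cross-tissue sharing of ASE against a permutation null with
    direction-concordance tests, and tests differential allelic imbalance
    between clinical groups or paired timepoints with beta-binomial
    likelihood-ratio tests. Includes a synthetic-data generator with
    beta-binomial overdispersion, reference bias, sequencing error, and
    two-tissue study designs so the whole pipeline is testable end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
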