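Package: umispike
Title: Spike-In Simulation and Benchmarking of Low-Frequency ctDNA Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking variant callers on circulating tumour DNA
    (ctDNA) sequencing data. Provides a spike-in read simulator that injects a
    panel of known single-nucleotide variants into cfDNA-like paired-end reads
    at controlled low allele frequencies and target depths, a synthetic unique
    molecular identifier (UMI) encoder that partitions PCR-duplicate read sets
    into UMI families by Poisson sampling, a variant filtering and annotation
    pipeline (depth/quality thresholds, dbSNP exclusion, COSMIC annotation),
    and evaluation utilities that score call sets against a spike-in truth set
    (true positives, putative false positives), compute database-annotated
    fractions, and tabulate exclusive multi-caller intersections. All inputs
    can be generated as small synthetic fixtures, so the full pipeline runs
    offline and deterministically from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    Biostrings,
    IRanges,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
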