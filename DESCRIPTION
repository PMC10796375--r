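Package: sixmer
Title: 6mer Seed Viability Analysis of RISC-Bound Small RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the toxicity potential of RISC-bound small RNA
    populations through the viability associated with their 6mer seeds
    (guide-strand positions 2-7). Builds sequence-by-sample read count
    tables from small RNA-seq FASTQ files, annotates reads with RNA type,
    6mer seed and per-seed cell viability, normalizes to one million reads
    per sample, selects differentially RISC-loaded reads between two
    groups, and computes read-count-weighted viability distributions:
    box statistics with Kruskal-Wallis group comparison, 1%-binned
    viability curves, and position-wise seed nucleotide composition.
    Includes a synthetic data generator with ground truth for validating
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
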