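Package: imputeqc
Title: Harmonize, Impute, Merge and Quality-Control Multi-Platform Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining genome-wide genotype datasets produced on
    heterogeneous genotyping platforms into one analysis-ready probabilistic
    genotype set. Covers genome-build coordinate conversion via precomputed
    map tables, strand harmonization against a phased reference panel
    (allele, minor-allele-frequency and linkage-disequilibrium criteria),
    chromosome segmentation for parallel imputation (fixed-size SNP blocks
    with marker buffers, or genomic windows with base-pair buffers and
    centromere-aware merging), a deterministic nearest-haplotype imputer for
    end-to-end testing, masked-genotype evaluation (concordance and allelic
    R-squared by minor-allele-frequency bin), merging of Oxford GEN
    probability files with companion info-metric files under
    position-and-allele cross-matching rules, post-merge quality-control
    summary tables, and population-structure analysis (KING-robust kinship,
    LD pruning, principal components). A seeded synthetic-data generator
    emulates multi-platform study designs so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
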