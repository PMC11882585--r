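Package: methdmc
Title: Differential CpG Methylation and Resampling-Based Enrichment for
    Two-Group RRBS Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing CpG methylation between two groups of
    reduced-representation bisulfite sequencing (RRBS) samples, such as two
    cattle breeds. Implements SNP-aware filtering of cytosine positions,
    per-CpG differential methylation testing by binomial logistic regression
    (equivalent to the G-test on pooled counts) with Benjamini-Hochberg false
    discovery rate control, and an empirical null built from random control
    cytosine subsets for testing enrichment of differentially methylated
    cytosines near SNPs, near reference position sets, in runs of adjacent
    sites (stretches), and within repeat-element classes. Includes projection
    of differential sites onto low-coverage multi-stage data sets, sample-level
    quality control with principal component analysis, a fully seeded
    synthetic-data generator with known ground truth, and a deterministic
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    vcfR,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
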