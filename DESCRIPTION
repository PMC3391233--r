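Package: ccchsurvey
Title: Genome-Wide Survey Toolkit for CCCH Zinc-Finger Gene Families
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide surveys of
    CCCH-type zinc-finger gene families. Scans protein sequences for the
    degenerate-spacer motif consensus C-Xa-C-Xb-C-X3-H, classifies and
    tallies motif classes, and builds per-class sequence-logo profiles.
    Builds neighbor-joining trees from protein alignments with bootstrap
    support and assigns family groups from supported clades. Classifies
    duplicate gene pairs as tandem or segmental, estimates Ka and Ks by
    the Nei-Gojobori (1986) method, calls selection mode, and dates
    duplication events from synonymous divergence. Scans promoter regions
    on both strands for stress-responsive cis-element cores (ABRE, DRE),
    and quantifies relative expression from qPCR Ct tables by the
    2^-delta-delta-Ct method. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable
    end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
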