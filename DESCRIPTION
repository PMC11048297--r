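Package: editscape
Type: Package
Title: Differential A-to-I RNA Editing Analysis for Drug-Sensitivity Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies adenosine-to-inosine (A>I(G)) RNA-editing sites from
    strand-aware pileup count tables, applies a filter cascade (edited-read
    and allele-frequency thresholds, cohort prevalence, genomic-variant
    subtraction), tests for differential editing between drug-sensitivity
    groups with a beta-binomial likelihood-ratio test, computes the Alu
    Editing Index, stratifies samples by IC50 quartiles, and validates
    differentially edited sites against progression-free survival with
    Kaplan-Meier and log-rank analysis. Ships a synthetic-data generator
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment, GenomicRanges
Imports: methods, stats, utils, tools, S4Vectors, IRanges, survival,
    jsonlite, yaml, vcfR, rtracklayer
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'editscape-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'EditingExperiment-methods.R'
    'io-formats.R'
    'synthetic-data.R'
    'site-calling.R'
    'diff-editing.R'
    'cohort-analysis.R'
    'survival-validation.R'
    'pipeline.R'
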