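Package: cnadose
Title: Gene-Dosage Attribution of Expression Deregulation in Tumor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying how much of a tumor's transcriptome
    deregulation is attributable to copy-number gene dosage. Segments
    marker-level log2 copy ratios with a 5-state hidden Markov model, filters
    copy-number alterations, computes per-tumor altered-genome burden and
    gene-level copy status, calls per-tumor expression status against a
    control baseline, runs permutation-based SAM differential expression,
    cross-tabulates deregulation against copy status, decomposes burden by
    chromosome arm with forward stepwise regression, bounds dosage-driven
    deregulation with exclusive-set and recurrence logic, and relates burden
    and expression profiles to patient survival. Includes a synthetic-cohort
    generator with planted ground truth and utilities that recompute the
    headline statistics of a published cervical carcinoma cohort shipped as
    plain-text tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    survival,
    ape,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
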