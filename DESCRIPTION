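Package: deciduoscreen
Title: Decidual Pathway Profiling and Endometrial Defect Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Day-normalized percentile scoring of decidual marker genes
    (SCARA5, DIO2) and uterine natural killer (uNK) cell abundance in
    timed endometrial biopsies, with rule-based classification of
    decidual-pathway defects (decidualization failure, excessive decidual
    senescence, uNK-cell deficiency) and cohort-level contingency
    statistics.  Includes the supporting single-cell computations:
    knee-point cell calling on barcode read distributions, quality-control
    filtering of digital gene expression matrices, graph-diffusion
    imputation, midpoint marker partitioning, rank-sum marker tests,
    figure-of-merit guided k-means co-expression modules, and the
    in vitro/in vivo gene-pair correlation congruency statistic.  A
    synthetic-data module generates cohorts, count matrices and barcode
    read distributions with known ground truth so the whole pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
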