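Package: fluidERT
Title: Endometrial Receptivity Staging from Uterine-Fluid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A noninvasive endometrial receptivity test built on uterine-fluid
    RNA-seq. The package simulates stage-timed uterine-fluid expression
    cohorts, normalizes fragment counts to FPKM and log2 units, detects
    stage-associated genes by per-gene ANOVA with Benjamini-Hochberg FDR and
    Tukey HSD post hoc comparisons, identifies weighted co-expression modules
    and their intramodular hub genes, assembles a marker panel by all-pairwise
    Tukey filtering plus random-forest dual-importance ranking, trains and
    cross-validates a three-class receptivity classifier with a
    probability-threshold no-call rule, interprets predicted stage as
    window-of-implantation displacement, and associates calls with pregnancy
    outcomes by exact contingency-table tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    MASS,
    jsonlite,
    yaml,
    withr,
    data.table
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
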