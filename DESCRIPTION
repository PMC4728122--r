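Package: TP53proxy
Title: Multi-Evidence TP53 Status Calling and Expression-Signature
    Performance Re-Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates CCLE-style mutation calls, copy-number ratios and
    MAS5-150 expression values into a rule-based TP53 inactivation call per
    cancer cell line, then re-evaluates a binary drug-sensitivity signature
    (sensitivity, specificity, PPV, NPV, response rate) under
    filter-then-re-evaluate and borderline-removal scenarios. Includes the
    per-sample trimmed-mean rescaling that defines the expression units all
    cutoffs depend on, and a synthetic multi-omic cohort generator so that
    proxy behaviour of a signature with respect to TP53 status can be
    demonstrated as a testable property without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'normalize.R'
    'caller.R'
    'evaluate.R'
    'synthetic.R'
    'pipeline.R'
    'TP53proxy-package.R'
biocViews: Transcriptomics, CopyNumberVariation, Pharmacogenomics,
    Classification
RoxygenNote: 7.3.3
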