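Package: invasig
Title: Derivation and Survival Validation of Tumor Invasion Gene Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
        role = c("aut", "cre"))
Description: Tools for deriving a gene-expression signature of migratory
    tumor cells from two-class two-channel microarray data and validating
    its prognostic value in survival cohorts. Implements Significance
    Analysis of Microarrays (SAM) with permutation-based false discovery
    rate estimation, global LOWESS normalization and probe-to-gene
    collapsing, a Minn-style leave-one-out cross-validated Cox risk index
    with top-quantile stratification, Kaplan-Meier and (weighted) log-rank
    comparison, an empirical random-signature null for signature
    specificity, multivariate Cox adjustment for clinical covariates, and
    the Creighton-style per-patient signature-correlation R value. A
    synthetic-data module generates two-class expression matrices and
    proportional-hazards survival cohorts with known planted structure so
    that every stage of the pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    MASS,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cox-batch.R'
    'io.R'
    'null.R'
    'pipeline.R'
    'preprocess.R'
    'risk.R'
    'rvalue.R'
    'sam.R'
    'simulate.R'
    'survival-core.R'
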