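Package: lobsuite
Title: Integrative Molecular Subtyping and Survival Modelling for Lobular Breast Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of multi-omic breast cancer
    cohorts, centred on invasive lobular carcinoma. Provides consensus
    clustering of gene expression with stability-based subtype assignment
    (including an explicit unassigned class), signal-to-noise differential
    expression ranking with gene set enrichment analysis, multi-omic subtype
    characterization (mutation burden, arm-level copy number, protein
    epitopes), cross-cohort subtype validation, stratified Cox
    likelihood-ratio screening of molecular features, and a
    conditional-inference survival tree built on log-rank scores. A bundled
    synthetic multi-omic cohort generator with known ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    limma,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
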