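Package: mesoscore
Title: Mesenchymal Subtype Scoring and Stromal Signature Analysis for
    High-Grade Serous Ovarian Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a 15-gene median-threshold classifier for the
    Mesenchymal (Mes) molecular subtype of high-grade serous ovarian
    carcinoma (HGSC), single-sample gene-signature z-scores, and a signed
    stromal-signature contrast comparing omental-metastasis stroma to
    primary-ovarian stroma.  Provides concordance statistics between
    classification schemes (Cohen's kappa, per-class accuracy, two-sided
    Fisher exact tests of subtype-by-group contingency tables),
    association of signature scores with annotated cell-type content,
    and a synthetic bulk-tumor cohort generator that mixes fibroblast,
    cancer-cell and immune archetype expression profiles with
    site-dependent stromal identity, supplying ground truth for every
    pipeline stage.  Readers and writers cover tab-delimited expression
    matrices, sample annotation tables and GMT gene-set files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
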