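Package: megalfc
Title: Cross-Study Mega-Analysis of Case/Control Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pools per-gene log2 fold changes across independent case/control
    expression studies ("mega-analysis") under fixed-effect and
    DerSimonian-Laird random-effect models, with Cochran's Q / I-squared
    heterogeneity-driven model selection, a sensitivity variant that pools
    only the top half of datasets per gene ("partial mega-analysis"), an
    asymmetric fold-change significance filter, QQ diagnostics of per-study
    z-scores, hypergeometric gene-set overlap and over-representation
    analysis with Benjamini-Hochberg correction, and study-level moderator
    regression on sample size, region and study date. Includes a synthetic
    multi-study generator with planted effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
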