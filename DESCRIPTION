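Package: metamux
Title: Multiplex Meta-Analysis of Differential Gene Expression Across Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines differential-expression evidence from multiple
    independent expression studies measured on heterogeneous platforms.
    Per study, probes are scored with directional (one-sided) Welch
    t-tests and log2 fold-changes with sampling variances; evidence is
    pooled per gene with Fisher's omnibus p-value combination over all
    probes across all studies and with an inverse-variance fixed-effects
    meta fold-change. Gene prioritizations are evaluated against
    signature gene sets with ROC curves and AUC. A synthetic multi-study
    data generator with planted effects and ground truth makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
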