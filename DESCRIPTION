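Package: splitSulfur
Title: Local and Systemic Response Classification for Split-Root
    Sulfate-Resupply RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for split-root nutrient-resupply RNA-seq
    experiments, built around the rice sulfur-deficiency design with nine
    sample groups (control, deficiency, homogeneous resupply and the two
    split-root halves under heterogeneous resupply). Provides a
    negative-binomial count simulator with planted response classes,
    FPKM quantification and replicate-correlation QC, a fully specified
    negative-binomial Wald test for two-group contrasts with
    Benjamini-Hochberg correction, deterministic set-algebra
    classification of deficiency-responsive genes into local, systemic,
    simultaneous and non-responsive recovery classes in roots (and
    homogeneous/heterogeneous response classes in shoots), hypergeometric
    term over-representation, and a single-config pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
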