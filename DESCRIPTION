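Package: metacohort
Title: Multi-Cohort Transcriptome Harmonization and Expression-Outcome
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Harmonizes feature-by-sample expression matrices from several
    colorectal-cancer cohorts into a single gene-level meta-cohort:
    per-feature mixed-effects removal of center, scan-batch and
    technical-metric effects, probeset-to-gene collapse by the first
    principal component, quantile normalization and inverse-probability
    weighted median/MAD standardization to a designated reference cohort.
    Downstream tools associate gene expression tertiles with relapse and
    overall survival (Cox proportional hazards, Kaplan-Meier) and with
    tumor stage (linear model), filter differential-expression tables and
    score gene-set overlaps, and compute delta-delta-Ct and ChIP
    percent-input quantities. A synthetic multi-cohort generator with
    known technical structure and survival ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    lme4,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
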