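Package: metaboresponse
Title: Statistical Workflow for Multi-Platform Metabolomic Intervention Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the metabolomic effects of weight-loss
    interventions in paired (baseline / 4-week) multi-platform studies:
    per-subject log2 fold-change derivation and principal component
    analysis with per-component group tests; per-feature linear
    mixed-effects interaction modelling with restricted maximum
    likelihood, Wald contrasts against a control arm and
    Benjamini-Hochberg false discovery rate control; confounder-adjusted
    model variants and a group-size power simulation; NIPALS partial
    least squares regression against clinical factors with
    cross-validated Q2 and permutation-based model validation and
    feature selection; cross-intervention congruence summaries; lipid
    shorthand parsing and free fatty acid to acyl-chain matching; and a
    synthetic-study generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mixOmics,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
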