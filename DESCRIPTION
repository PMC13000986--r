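Package: seqherb
Title: Multilevel Meta-Analysis of Plant Responses to Sequential Herbivory
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-analysis of sequential-herbivory experiments, in
    which a plant is attacked first by an inducing herbivore and later by a
    subsequent herbivore. Computes Hedges' g standardized mean differences and
    log odds ratios from raw study summaries with outcome-specific sign
    conventions, fits three-level random-effects meta-analytic models by REML
    (sampling error, treatment-within-study and between-study variance
    components, with an optional phylogenetically correlated taxon effect),
    reports multilevel I-squared, omnibus moderator Q-tests and prediction
    intervals, and provides publication-bias diagnostics (cumulative
    meta-analysis by publication year, funnel coordinates, Egger-type
    asymmetry regressions) and sensitivity analyses (leave-one-species-out
    refits, binary-outcome validation). Includes a synthetic-data generator
    that emulates the nested structure of extracted literature datasets so
    every pipeline stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    methods,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
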