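Package: screenflow
Title: Criterion-Wise LLM-Assisted Title and Abstract Screening for Systematic Reviews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for first-stage (title and abstract) study selection in
    systematic reviews with a pluggable automated judge. Bibliographic exports are
    cleaned and uniquely identified, optionally embedded into an ID-addressable
    index, and each record is evaluated against a set of named Boolean
    inclusion/exclusion criteria by a judging backend (a live language model or a
    deterministic simulator). Per-criterion verdicts are combined into
    include/exclude decisions by a strict all-criteria-true rule or by a random
    forest trained on the criterion verdicts with adaptive stratified
    cross-validation. Decisions are compared against human screening labels with a
    full evaluation suite: confusion matrices, precision/recall/specificity/F1,
    Matthews correlation coefficient, Cohen's kappa, prevalence-adjusted
    bias-adjusted kappa (PABAK), workload-reduction accounting, and per-criterion
    Pearson correlations. A synthetic-corpus generator with known per-criterion
    sensitivity and false-positive rates makes the whole pipeline testable
    offline, including closed-form parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    randomForest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
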