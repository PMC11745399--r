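# screenflow

Criterion-wise, LLM-assisted title/abstract screening for systematic reviews,
with a full agreement and workload-reduction evaluation suite and an offline
simulator for every stage.

## The problem

First-stage study selection ("screening 1") in a systematic review requires two
researchers to read the titles and abstracts of thousands of database hits and
apply pre-registered inclusion/exclusion criteria. The task is laborious and
the class balance extreme: typically only a few percent of records pass.
A language model can stand in as the second screener: each record — the
concatenation of its title and abstract — is judged against every named
criterion separately, returning a Boolean verdict plus a brief justification
per criterion. Records where the machine and the first human reviewer agree no
longer need a second human read; everything else (disagreements, records the
pipeline failed to process, records dropped in preprocessing) remains human
workload.

`screenflow` implements that pipeline end to end for researchers in evidence
synthesis and for methodologists studying screening automation:

- **records** — read tabular exports (`title`, `abstract`, `screening1`, …),
  drop empty-abstract rows, duplicates and non-English records, build the
  joined `Record` text and deterministic unique ids.
- **store** — an ID-addressable embedded index (batched embedding, exact
  retrieval by identifier only, integrity validation); similarity search is
  deliberately not exposed.
- **judge** — the prompt/response contract (JSON verdicts per criterion),
  a robust parser that recovers JSON from prose-prefixed responses and
  normalizes string Booleans, exponential-backoff retries for rate limits
  (2^attempt seconds, up to five attempts), and checkpointed corpus runs with
  disjoint succeeded/missing bookkeeping. Backends are pluggable; a
  deterministic mock makes the whole pipeline testable offline.
- **decide** — two decision rules: the strict *all-criteria-true* rule
  (include iff every criterion verdict is true) and a random-forest combiner
  (100 trees, balanced class weights) with adaptive stratified
  cross-validation, `k = min(5, max(2, minority class size))`, producing
  out-of-fold predictions.
- **evaluate** — confusion matrix, precision/recall/specificity/F1, Matthews
  correlation coefficient (MCC), Cohen's kappa, the prevalence-adjusted
  bias-adjusted kappa **PABAK = 2·p₀ − 1** (p₀ = observed agreement), workload
  reduction against the *originally identified* record count, and per-criterion
  Pearson correlations with the screening-1 label.
- **simulate** — synthetic corpora with known prevalence π, per-criterion
  sensitivity *s* and false-positive rate *f*, and a record-level failure
  rate. Under the all-true rule with independent criteria the expected
  operating point is closed form: recall = ∏ sₖ, specificity = 1 − ∏ fₖ,
  which the simulator recovers empirically.

The screening-1 criteria of three published reviews (musculoskeletal
physiotherapy economics, hereditary neuropathy treatment, AI cost-effectiveness
in healthcare) ship as example YAML configs under
`system.file("extdata", "criteria", package = "screenflow")`.

## Worked example

A fully offline run: simulate a 1,000-record corpus at 8 % inclusion
prevalence with three noisy criteria and a 1 % processing-failure rate, decide
by the all-true rule, and evaluate against the simulated human labels.

```r
library(screenflow)

profiles <- list(
  criterion_profile("population",   sensitivity = 0.92, false_positive_rate = 0.15),
  criterion_profile("intervention", sensitivity = 0.90, false_positive_rate = 0.20),
  criterion_profile("outcome",      sensitivity = 0.88, false_positive_rate = 0.10))
cfg     <- simulation_config(n_records = 1000, prevalence = 0.08, profiles,
                             failure_rate = 0.01, seed = 28)
dataset <- generate_review(cfg)
sim     <- simulate_verdicts(dataset, cfg)

decisions <- all_true_rule(sim$matrix)
ev <- evaluate_run(decisions, dataset, matrix = sim$matrix)
ev$metrics
#> <metrics_report> precision=0.9701 recall=0.7831 specificity=0.9978 f1=0.8667 mcc=0.8616
ev$agreement
#> <agreement_stats> p0=0.9798 kappa=0.8559 pabak=0.9596
ev$workload
#> <workload_report> correct=969 of 1000 | remaining=31 | reduction=97%
```

Reading the output: of 989 processed records the machine agreed with the human
reviewer on 969, so a second reviewer needs to read only the 31 remaining
records (disagreements plus the 11 processing failures) — a 97 % workload
reduction. Recall 0.78 sits close to the closed-form expectation
∏ s = 0.92·0.90·0.88 ≈ 0.73 for the strict rule, whose known cost is false
negatives: every single false criterion excludes. The forest combiner trades
the other way — at this prevalence its balanced class weights push recall to
≈ 0.99 while specificity drops, the characteristic true-positive/true-negative
exchange between the two rules:

```r
rf <- rf_out_of_fold(sim$matrix, dataset$records$human_screen1, seed = 28)
evaluate_run(rf, dataset, matrix = sim$matrix)$metrics
#> <metrics_report> precision=0.2124 recall=0.9880 specificity=0.6645 f1=0.3497 mcc=0.3708
```

Live screening runs work the same way: `read_screening_table()` +
`preprocess_records()` on your export, `read_criteria()` on a criteria config,
and `screen_corpus()` with a backend adapter for your model endpoint (the
backend contract is prompt text in, response text out, with
`rate_limit_error()` / `backend_error()` for the failure taxonomy).
A thin command-line front end with `simulate`, `preprocess`, `embed`,
`screen`, `decide` and `evaluate` subcommands lives at
`system.file("cli", "screenflow.R", package = "screenflow")`.

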