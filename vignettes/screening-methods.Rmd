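---
title: "Criterion-wise screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criterion-wise screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenflow)
```

## The screening model

First-stage study selection judges each bibliographic record — the
concatenation of its title and abstract — against a set of named Boolean
inclusion/exclusion criteria. `screenflow` decomposes the machine's role the
same way a human screener's instructions are written: one verdict per
criterion, each with a brief justification, rather than a single opaque
include/exclude call. Two decision rules then combine the per-criterion
verdicts:

* **All-criteria-true.** A record is machine-included iff every criterion
  verdict is true. The rule is maximally stringent: one false criterion
  excludes. Under conditional independence of the criterion verdicts given
  the true label, its operating point is closed form — recall $\prod_k s_k$
  and specificity $1 - \prod_k f_k$, where $s_k$ is criterion $k$'s
  sensitivity and $f_k$ its false-positive rate
  (`expected_operating_point()`). Stringency therefore compounds: even good
  per-criterion sensitivity (say 0.9 per criterion) yields modest record-level
  recall once several criteria multiply.
* **Random-forest combiner.** `rf_out_of_fold()` treats the verdict matrix as
  features and the human screening-1 label as the target, so the model can
  learn that some criteria matter more than others and that a record may
  deserve inclusion despite one false criterion. Every reported decision is
  out of fold: the forest voting on a record never saw that record's fold.

Evaluation treats the machine as a second rater against the first human
reviewer. Beyond the usual confusion-matrix metrics, two chance-corrected
agreement statistics are reported. Cohen's kappa corrects observed agreement
$p_0$ by the marginal-product chance agreement $p_e$; at screening prevalence
(a few percent includable), $p_e$ is dominated by the excluded class, which
makes kappa hard to interpret across reviews. PABAK — the prevalence-adjusted
bias-adjusted kappa — fixes chance agreement at $0.5$:
$\mathrm{PABAK} = 2p_0 - 1$, ranging from $-1$ through $0$ (agreement at
chance) to $+1$. MCC plays the analogous role among the classification
metrics: it uses all four confusion cells and stays informative under heavy
class imbalance.

## Workload accounting

The practical payoff of a machine second screener is the number of records a
human second reviewer no longer needs to read. `workload_reduction()` counts
`correct` — records where machine and first reviewer agree, *among records the
pipeline actually processed* — against the number of records the review's
search originally identified, not the preprocessed count. Everything the
pipeline could not handle stays in the human pile: records dropped during
preprocessing (no abstract, duplicate, non-English), records whose judging
failed, and records where machine and human disagree. A judging failure is
represented internally as an all-false verdict row (it can never satisfy the
all-true rule), but `evaluate_run()` with a `criteria_matrix` excludes such
records from the agreement count — a forced row is not a decision, so a failed
record is never "correct", and `remaining` is always at least the number of
failures.

Percentages are rounded half-away-from-zero to integer percent
(`round_half_away()`). This rule reproduces every unambiguous printed
workload percentage in the published review data the test suite encodes
(4294/4662 → 92, 1539/1741 → 88, 4329/4662 → 93, 4130/4662 → 89). One
published figure for the smallest review is internally inconsistent (a
correct count of 27 of 66 printed as 40 %, where 27/66 rounds to 41 and the
printed remaining-workload count implies 26); we flag it and do not force a
rounding rule from it. Because integer rounding and averaging over judging
runs do not commute, `summarize_workload()` reports both orders
(round-the-mean and mean-of-rounded) rather than silently choosing one.

## The judge contract and its failure modes

`build_prompt()` renders the record once, every criterion key and
instruction in display order, and an explicit directive to answer with only a
JSON object keyed by criterion, each entry a Boolean `value` plus a brief
`justification`. The exact wording is a package choice; the contract — JSON
only, one key per criterion, Boolean plus justification — is what the parser
and tests enforce, and a custom template can be supplied where a backend
needs different phrasing.

Real model output violates the contract in predictable ways, so
`parse_verdicts()` is built to be total: for any input it returns either one
verdict per criterion or a typed parse error, never a partial map. It scans
for the first balanced, parseable JSON object (tolerating prose before and
after — the classic "Here is the output in the requested format:" preamble),
accepts bare Booleans and string Booleans (`"True"`), and fills criteria that
are absent or uninterpretable with the default `value = FALSE`. False is the
conservative default: under the all-true rule it pushes the record toward
exclusion-by-machine, which at worst returns the record to the second
reviewer's pile; a default of true could silently include.

Transient failures are retried: a rate-limit error after attempt $a$ waits
$2^a$ seconds (2, 4, 8, 16 s) for up to five attempts; the attempt counter
starts at 1, so four delays precede the fifth and final attempt. Non-rate-limit
errors and parse failures are not retried — they are deterministic given the
same input, so retrying wastes budget — and the record moves to the missing
set with its failure class (`rate_limit`, `parse`, `other`) recorded. The
clock is injected (`sleep_fn`), so the schedule is testable without real
delays.

`screen_corpus()` maintains the succeeded and missing sets as disjoint maps,
checkpoints the full state atomically (temp file + rename) after every batch
of 20 records, and on resume re-judges only records not yet succeeded;
previously failed records get another chance. A checkpoint that fails to
parse refuses to resume rather than guessing. Records are processed
sequentially in this implementation; the `concurrency_limit` field (default
5) is validated and carried in the run configuration so the same
configuration is portable to asynchronous backends, and the checkpoint and
disjointness semantics do not depend on execution order.

## The store

Each judgment needs exactly one record's text, so the index is an exact-ID
store: `fetch_by_id()` returns the payload for that identifier or a
not-found error — never a nearest neighbour, which on near-duplicate corpora
(common after imperfect deduplication) could silently judge the wrong
record. Embeddings are computed in batches of 100 and persisted with a JSON
manifest; `validate_index()` reports ids missing from or extraneous to the
index before any screening run. The default embedder is a deterministic
hash-based pseudo-embedding (dimension 64, values in $[-1,1]$): it carries no
semantic signal, which is irrelevant for exact-ID retrieval, and it makes the
whole pipeline runnable and testable offline. Live embedding models are
adapters behind the same function signature, and the stage is optional — the
judge can read `record_text` directly from the dataset.

## The simulator

`generate_review()` and `simulate_verdicts()` define the study conditions
under which the pipeline is tested: $n$ records with i.i.d. Bernoulli($\pi$)
inclusion labels; per-criterion verdicts drawn independently given the true
label with probability $s_k$ (includable) or $f_k$ (excludable); a
record-level failure probability. All randomness in a run flows from one
seed, drawn in a fixed order (failures first, then the verdict matrix
row-wise), so a seed pins the entire output; the generator restores the
caller's RNG state. Synthetic abstracts are templated English sentences long
enough to exercise prompt construction, and they embed the record id, which
is how the offline mock backend resolves prompts to records.

Test conditions used by the suite: parameter-recovery runs use $n = 20{,}000$
records at $\pi = 0.5$ with two criteria at $s = 0.9$, $f = 0.2$, asserting
the empirical operating point within three binomial standard errors of the
closed form; forest-sanity runs use $n = 200$ with three criteria and labels
equal to the criterion conjunction (perfectly separable), requiring
out-of-fold accuracy $\ge 0.95$; a small-corpus shape check draws $n = 66$ at
$\pi = 45/66$, the class shape of the smallest encoded review.

What the simulator does *not* emulate: criterion verdicts correlated beyond
the true label (real models err systematically on related criteria), record
text whose difficulty drives failure (failures here are i.i.d., whereas real
processing failures cluster on malformed records), reviewer disagreement (one
ground-truth label), and any actual language understanding. Passing tests
therefore demonstrate that the machinery — parsing, bookkeeping, decision
rules, metrics — is correct under known generative conditions, not that any
particular language model screens well.

## Numerical and design choices

* **Duplicate definition:** case-folded, whitespace-normalized equality of
  (title, abstract); first occurrence kept.
* **Record text:** labeled join `"Title: … Abstract: …"` by default (clearer
  for a judge); a plain space-join variant is selectable.
* **Language filter:** the `language` column when present (empty tags pass);
  a custom detector is pluggable; nothing is guessed from the text by
  default.
* **Unknown `screening1` labels** abort preprocessing with a typed error:
  the human label is the ground truth every comparison rests on.
* **Record ids** are assigned from surviving row order (`rec-00001`, …), so
  preprocessing is deterministic and idempotent.
* **Forest configuration:** 100 trees; class weights inversely proportional
  to class frequency ($n / (2 n_c)$, "balanced"); stratified folds with
  $k = \min(5, \max(2, \text{minority class size}))$ and an error below two
  minority members; majority-vote threshold 0.5 on the out-of-fold vote
  fraction. Stratification is imposed so every fold contains both classes —
  the reason the fold count adapts at all. Constant verdict columns warn but
  do not abort. The combiner is fit per screening run (one review × one
  judge), not pooled across runs.
* **Undefined metrics** (zero denominators: e.g. precision with no positive
  predictions, kappa at $p_e = 1$) are `NA` flags, never 0 and never errors,
  so downstream aggregation cannot silently average them away.
* **Seeds** default to 28 wherever one is needed; judge sampling defaults
  are temperature 0, top-p 0.95, a 25,000-token context window and unlimited
  response length, chosen for reproducibility and so differently sized
  models face the same input budget.

## Known limitations

Sequential execution makes wall-clock time linear in corpus size; live-model
adapters and true concurrency are out of scope here, as are criteria
refinement loops, full-text (screening 2) logic, fuzzy cross-database
deduplication, and calibration of the simulator to any specific model's
empirically measured per-criterion behaviour. The shipped criteria configs
are data, not logic: the package does not interpret their medical content.
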