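#' Per-criterion behaviour profile for a simulated judge
#'
#' Describes one criterion's verdict process as two conditional
#' probabilities: `sensitivity`, the probability the simulated judge
#' answers `true` on a truly includable record, and `false_positive_rate`,
#' the probability it answers `true` on a truly excludable record. A
#' perfect judge has sensitivity 1 and false-positive rate 0.
#'
#' @param key Criterion key.
#' @param sensitivity Probability in `[0, 1]`.
#' @param false_positive_rate Probability in `[0, 1]`.
#' @return A `criterion_profile` list.
#' @export
criterion_profile <- function(key, sensitivity, false_positive_rate) {
  stopifnot(is_string(key),
            sensitivity >= 0, sensitivity <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1)
  structure(list(key = key, sensitivity = sensitivity,
                 false_positive_rate = false_positive_rate),
            class = "criterion_profile")
}

#' Generative configuration for a synthetic screening corpus
#'
#' @param n_records Number of records (`>= 10`).
#' @param prevalence Proportion of truly includable records, in `(0, 1)`.
#'   Screening corpora are typically heavily imbalanced (a few percent
#'   includable), which is why the downstream metrics emphasise MCC and
#'   PABAK.
#' @param profiles List of [criterion_profile()]s, one per criterion.
#' @param failure_rate Probability a record's judging fails outright, in
#'   `[0, 1)`.
#' @param seed Integer seed; all randomness of a simulation run flows from
#'   it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_records, prevalence, profiles,
                              failure_rate = 0, seed = 28L) {
  n_records <- as.integer(n_records)
  if (n_records < 10L) sf_stop("screenflow_config_error", "n_records must be >= 10")
  if (!(prevalence > 0 && prevalence < 1)) {
    sf_stop("screenflow_config_error", "prevalence must lie strictly in (0, 1)")
  }
  if (!(failure_rate >= 0 && failure_rate < 1)) {
    sf_stop("screenflow_config_error", "failure_rate must lie in [0, 1)")
  }
  if (length(profiles) == 0 || !all(vapply(profiles, inherits, logical(1), "criterion_profile"))) {
    sf_stop("screenflow_config_error", "profiles must be a non-empty list of criterion_profile")
  }
  keys <- vapply(profiles, `[[`, character(1), "key")
  if (anyDuplicated(keys)) sf_stop("screenflow_config_error", "profile keys must be unique")
  structure(list(n_records = n_records, prevalence = prevalence,
                 profiles = stats::setNames(profiles, keys),
                 failure_rate = failure_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

# Templated synthetic title/abstract. The record id is embedded in the text so
# offline mock backends can resolve which record a prompt is about, and the
# abstract is long enough to exercise prompt construction.
synthetic_record_text <- function(record_id, includable) {
  topic <- if (includable) "a treatment relevant to the review question" else
    "a topic outside the review question"
  title <- sprintf("Synthetic study %s: an investigation of %s", record_id, topic)
  abstract <- paste(
    sprintf("Background: this synthetic abstract (record %s) describes %s.", record_id, topic),
    "Methods: a generated cohort was observed under controlled conditions.",
    "Results: outcome measures were recorded and summarized for evaluation purposes.",
    "Conclusions: the findings are synthetic and carry no clinical meaning."
  )
  list(title = title, abstract = abstract)
}

#' Generate a synthetic review corpus with known ground truth
#'
#' Draws `n_records` records whose human screening-1 labels are i.i.d.
#' Bernoulli with the configured prevalence, wrapped in templated
#' title/abstract text that embeds the record id. The output is a regular
#' `review_dataset` (with `original_total = n_records`) usable by every
#' downstream stage; a fixed seed reproduces it exactly.
#'
#' @param config A [simulation_config()].
#' @param on_degenerate What to do if a draw yields a single class:
#'   `"regenerate"` (default) redraws the label vector (up to 1000 times),
#'   `"error"` aborts.
#' @return A `review_dataset` whose `records$human_screen1` holds the
#'   simulated ground truth.
#' @export
generate_review <- function(config, on_degenerate = c("regenerate", "error")) {
  stopifnot(inherits(config, "simulation_config"))
  on_degenerate <- match.arg(on_degenerate)
  n <- config$n_records

  labels <- with_seed_local(config$seed, {
    lab <- stats::runif(n) < config$prevalence
    tries <- 0L
    while (length(unique(lab)) < 2L) {
      if (on_degenerate == "error" || tries >= 1000L) {
        sf_stop("screenflow_degenerate_draw",
                "label draw produced a single class at prevalence %g", config$prevalence)
      }
      lab <- stats::runif(n) < config$prevalence
      tries <- tries + 1L
    }
    lab
  })

  ids <- sprintf("rec-%05d", seq_len(n))
  texts <- lapply(seq_len(n), function(i) synthetic_record_text(ids[i], labels[i]))
  records <- data.frame(
    record_id = ids,
    title = vapply(texts, `[[`, character(1), "title"),
    abstract = vapply(texts, `[[`, character(1), "abstract"),
    human_screen1 = labels,
    human_screen2 = NA,
    stringsAsFactors = FALSE
  )
  records$record_text <- paste0("Title: ", records$title, " Abstract: ", records$abstract)
  records <- records[, c("record_id", "title", "abstract", "record_text",
                         "human_screen1", "human_screen2")]

  structure(
    list(review_name = sprintf("synthetic (n=%d, prevalence=%g, seed=%d)",
                               n, config$prevalence, config$seed),
         records = records,
         original_total = n,
         preprocessed_total = n,
         dropped = c(empty_abstract = 0L, duplicate = 0L, language = 0L)),
    class = "review_dataset"
  )
}

#' Simulate per-criterion judge verdicts for a corpus
#'
#' For each record that does not fail outright (probability
#' `failure_rate`), every criterion verdict is drawn independently:
#' `true` with probability `sensitivity` if the record is truly includable,
#' with probability `false_positive_rate` otherwise (conditional
#' independence given the true label). Failed records get status
#' `"failed"` and an all-false row. The draw order is fixed (failures
#' first, then the verdict matrix row-wise), so a seed pins the entire
#' output.
#'
#' @param dataset A `review_dataset` carrying truth in `human_screen1`.
#' @param profiles List of [criterion_profile()]s (or a
#'   [simulation_config()], whose profiles and failure rate are used).
#' @param failure_rate Record-level failure probability.
#' @param seed Integer seed.
#' @return A list with `matrix` (a `criteria_matrix` with statuses) and
#'   `result` (an equivalent `screen_result` of `verdict_set`s,
#'   interchangeable with [screen_corpus()] output).
#' @export
simulate_verdicts <- function(dataset, profiles, failure_rate = 0, seed = 28L) {
  stopifnot(inherits(dataset, "review_dataset"))
  if (inherits(profiles, "simulation_config")) {
    failure_rate <- profiles$failure_rate
    seed <- profiles$seed
    profiles <- profiles$profiles
  }
  keys <- vapply(profiles, `[[`, character(1), "key")
  names(profiles) <- keys
  n <- nrow(dataset$records)
  truth <- dataset$records$human_screen1
  ids <- dataset$records$record_id

  drawn <- with_seed_local(seed, {
    failed <- stats::runif(n) < failure_rate
    values <- matrix(FALSE, nrow = n, ncol = length(keys),
                     dimnames = list(ids, keys))
    for (i in seq_len(n)) {
      if (failed[i]) next
      p <- vapply(profiles, function(pr) {
        if (truth[i]) pr$sensitivity else pr$false_positive_rate
      }, numeric(1))
      values[i, ] <- stats::runif(length(keys)) < p
    }
    list(failed = failed, values = values)
  })

  status <- ifelse(drawn$failed, "failed", "ok")
  cmat <- new_criteria_matrix(ids, keys, drawn$values, status)

  succeeded <- list()
  missing <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    if (drawn$failed[i]) {
      missing[[id]] <- new_verdict_set(id, status = "failed", attempts = 1L,
                                       failure_class = "other")
    } else {
      verdicts <- lapply(keys, function(k) {
        list(value = drawn$values[i, k],
             justification = sprintf("simulated verdict for %s", k))
      })
      names(verdicts) <- keys
      succeeded[[id]] <- new_verdict_set(id, verdicts = verdicts, status = "ok")
    }
  }

  list(matrix = cmat,
       result = structure(list(succeeded = succeeded, missing = missing),
                          class = "screen_result"))
}

#' Expected operating point of the all-true rule
#'
#' Under conditional independence of criterion verdicts given the true
#' label, the all-true rule includes a truly includable record only when
#' every criterion fires, so expected recall is the product of the
#' sensitivities; it wrongly includes an excludable record only when every
#' criterion false-fires, so expected specificity is one minus the product
#' of the false-positive rates.
#'
#' @param profiles List of [criterion_profile()]s.
#' @return List with `recall` and `specificity`.
#' @examples
#' p <- list(criterion_profile("a", 0.9, 0.2), criterion_profile("b", 0.9, 0.2))
#' expected_operating_point(p)  # recall 0.81, specificity 0.96
#' @export
expected_operating_point <- function(profiles) {
  s <- vapply(profiles, `[[`, numeric(1), "sensitivity")
  f <- vapply(profiles, `[[`, numeric(1), "false_positive_rate")
  list(recall = prod(s), specificity = 1 - prod(f))
}
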