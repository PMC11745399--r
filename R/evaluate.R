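#' Confusion matrix of machine decisions against human labels
#'
#' Counts the four agreement/disagreement cells between machine
#' include/exclude decisions and the human screening-1 labels, with
#' "included at screening 1" as the positive class.
#'
#' @param decisions A `decision_vector`, or a logical vector.
#' @param truth Logical vector of human screening-1 labels. If `decisions`
#'   is a `decision_vector` and `truth` is named (or `truth_ids` is given),
#'   alignment by record id is enforced.
#' @param truth_ids Optional record ids aligned with `truth`.
#' @return A `confusion` object: list with `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
confusion <- function(decisions, truth, truth_ids = NULL) {
  if (inherits(decisions, "decision_vector")) {
    ids <- decisions$record_id
    d <- decisions$decision
    if (!is.null(truth_ids) || !is.null(names(truth))) {
      tid <- truth_ids %||% names(truth)
      if (!setequal(ids, tid)) {
        sf_stop("screenflow_alignment_error",
                "decision and truth record ids do not match")
      }
      truth <- truth[match(ids, tid)]
    }
  } else {
    d <- as.logical(decisions)
  }
  truth <- as.logical(truth)
  if (length(d) != length(truth)) {
    sf_stop("screenflow_alignment_error",
            "decisions (%d) and truth (%d) differ in length", length(d), length(truth))
  }
  if (length(d) == 0) sf_stop("screenflow_alignment_error", "nothing to compare")
  structure(list(tp = sum(d & truth), fp = sum(d & !truth),
                 fn = sum(!d & truth), tn = sum(!d & !truth),
                 n = length(d)),
            class = "confusion")
}

#' Build a confusion object from the four cell counts
#'
#' @param tp,fp,fn,tn Nonnegative cell counts; positive class = included at
#'   screening 1.
#' @return A `confusion` object.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) sf_stop("screenflow_config_error", "confusion cells must be >= 0")
  n <- sum(cells)
  if (n < 1) sf_stop("screenflow_config_error", "confusion matrix must count at least one pair")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> n=%d\n            truth+  truth-\n  decided+  %6d  %6d\n  decided-  %6d  %6d\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from a confusion matrix
#'
#' Precision, recall (sensitivity), specificity, F1 and the Matthews
#' correlation coefficient. Any metric whose denominator is zero is
#' reported as `NA` (an explicit undefined flag), never as 0 and never as
#' an error, so aggregation across runs cannot silently average undefined
#' values.
#'
#' @param cm A `confusion` object.
#' @return A `metrics_report` list: `precision`, `recall`, `specificity`,
#'   `f1` in `[0, 1]` or `NA`; `mcc` in `[-1, 1]` or `NA`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) NA_real_ else (tp * tn - fp * fn) / denom
  structure(list(precision = precision, recall = recall,
                 specificity = specificity, f1 = f1, mcc = mcc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("<metrics_report> precision=%s recall=%s specificity=%s f1=%s mcc=%s\n",
              fmt(x$precision), fmt(x$recall), fmt(x$specificity), fmt(x$f1), fmt(x$mcc)))
  invisible(x)
}

#' Inter-rater agreement: observed agreement, Cohen's kappa, PABAK
#'
#' Treats the machine and the human reviewer as two raters. Observed
#' agreement is `p0 = (tp + tn) / n`. Cohen's kappa corrects `p0` by the
#' chance agreement `pe` expected from the raters' marginal proportions.
#' The prevalence-adjusted bias-adjusted kappa (PABAK) instead fixes chance
#' agreement at 0.5, giving `PABAK = 2 * p0 - 1`: robust when one class
#' dominates — the usual situation in screening, where most records are
#' excluded — and when the raters' inclusion thresholds differ. PABAK
#' ranges from -1 (disagreement on every record) through 0 (agreement at
#' chance level) to +1 (agreement on every record).
#'
#' @param cm A `confusion` object.
#' @return An `agreement_stats` list: `p0`, `kappa` (`NA` when `pe = 1`),
#'   `pabak`.
#' @export
agreement_stats <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  n <- cm$n
  p0 <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) + (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (p0 - pe) / (1 - pe)
  structure(list(p0 = p0, kappa = kappa, pabak = 2 * p0 - 1),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> p0=%.4f kappa=%s pabak=%.4f\n",
              x$p0, if (is.na(x$kappa)) "undefined" else sprintf("%.4f", x$kappa), x$pabak))
  invisible(x)
}

#' Workload reduction for a second human reviewer
#'
#' When the machine stands in as second reviewer, records on which it
#' agrees with the first human reviewer (`correct = tp + tn`) no longer
#' need a second human read. Everything else — disagreements, records the
#' pipeline failed to process, and records dropped during preprocessing —
#' remains second-reviewer workload. The denominator is therefore the
#' number of records the review's search originally identified, not the
#' preprocessed count.
#'
#' @param correct Number of records where machine and first reviewer agree,
#'   among processed records.
#' @param original_total Originally identified record count.
#' @return A `workload_report` list: `correct`, `original_total`,
#'   `remaining` (`original_total - correct`), `reduction_percent`
#'   (integer percent, half rounded away from zero).
#' @examples
#' workload_reduction(4294, 4662)  # remaining 368, reduction 92
#' @export
workload_reduction <- function(correct, original_total) {
  if (original_total < 1) sf_stop("screenflow_config_error", "original_total must be >= 1")
  if (correct < 0 || correct > original_total) {
    sf_stop("screenflow_accounting_error",
            "correct (%s) must lie in [0, original_total = %s]", correct, original_total)
  }
  structure(list(correct = correct,
                 original_total = original_total,
                 remaining = original_total - correct,
                 reduction_percent = round_half_away(100 * correct / original_total)),
            class = "workload_report")
}

#' @export
print.workload_report <- function(x, ...) {
  cat(sprintf("<workload_report> correct=%d of %d | remaining=%d | reduction=%d%%\n",
              x$correct, x$original_total, x$remaining, x$reduction_percent))
  invisible(x)
}

#' Summarize workload reduction across several judging runs
#'
#' Given per-run counts of correctly classified records (machine agrees
#' with the first reviewer), reports the mean, minimum and maximum
#' workload reduction. Because integer rounding and averaging do not
#' commute, both aggregation orders are reported: `mean_percent` rounds
#' the mean correct count once, `mean_of_percents` averages the per-run
#' integer percentages.
#'
#' @param correct_counts Integer vector, one correct count per run.
#' @param original_total Originally identified record count.
#' @return A list with `mean` (a `workload_report` at the rounded mean
#'   correct count), `min`, `max` (reports at the extreme counts), and
#'   `mean_of_percents`.
#' @export
summarize_workload <- function(correct_counts, original_total) {
  stopifnot(length(correct_counts) >= 1)
  per_run <- vapply(correct_counts, function(cc) {
    workload_reduction(cc, original_total)$reduction_percent
  }, numeric(1))
  list(mean = workload_reduction(round_half_away(mean(correct_counts)), original_total),
       min = workload_reduction(min(correct_counts), original_total),
       max = workload_reduction(max(correct_counts), original_total),
       mean_of_percents = mean(per_run))
}

#' Pearson correlation of each criterion with the screening-1 label
#'
#' Correlates every criterion's Boolean verdict column (coded 0/1) with the
#' human screening-1 label (0/1). With binary variables this Pearson
#' correlation is the point-biserial/phi coefficient; it indicates which
#' criteria track the human inclusion decision and in which direction.
#' Constant columns have no defined correlation and are flagged `NA`.
#'
#' @param matrix A `criteria_matrix`.
#' @param truth Logical human screening-1 labels aligned with
#'   `matrix$record_ids`.
#' @return A data frame (`criterion`, `r`) ordered by criterion key, class
#'   `correlation_matrix`.
#' @export
criterion_correlations <- function(matrix, truth) {
  stopifnot(inherits(matrix, "criteria_matrix"))
  truth <- as.numeric(as.logical(truth))
  if (length(truth) != length(matrix$record_ids)) {
    sf_stop("screenflow_alignment_error", "truth labels do not align with matrix rows")
  }
  keys <- sort(matrix$criterion_keys)
  r <- vapply(keys, function(k) {
    col <- as.numeric(matrix$values[, k])
    if (stats::sd(col) == 0 || stats::sd(truth) == 0) NA_real_
    else stats::cor(col, truth)
  }, numeric(1))
  structure(data.frame(criterion = keys, r = unname(r), stringsAsFactors = FALSE),
            class = c("correlation_matrix", "data.frame"))
}

#' Full evaluation of a screening run
#'
#' Convenience wrapper producing every evaluation output at once for one
#' decision vector: confusion matrix, classification metrics, agreement
#' statistics, and the workload report against the original record total.
#'
#' When `matrix` (a `criteria_matrix` carrying per-record judging status)
#' is supplied, records whose judging failed are excluded from the
#' confusion comparison: a forced all-false row is not a decision the
#' machine actually made, so such records never count as "correct" — they
#' stay in the residual second-reviewer workload even when their forced
#' exclusion happens to match the human label. The workload numerator is
#' then the agreements among processed records only, so `remaining` is
#' always at least the number of failed records.
#'
#' @param decisions A `decision_vector` covering all records of `dataset`.
#' @param dataset The `review_dataset` screened.
#' @param matrix Optional `criteria_matrix` whose `status` marks failed
#'   records; `NULL` treats every record as processed.
#' @return A list with `confusion`, `metrics`, `agreement`, `workload`,
#'   and `n_failed`.
#' @export
evaluate_run <- function(decisions, dataset, matrix = NULL) {
  stopifnot(inherits(dataset, "review_dataset"),
            inherits(decisions, "decision_vector"))
  ids <- dataset$records$record_id
  truth <- dataset$records$human_screen1
  d <- decisions$decision[match(ids, decisions$record_id)]
  if (anyNA(d)) {
    sf_stop("screenflow_alignment_error", "decisions do not cover every dataset record")
  }
  processed <- rep(TRUE, length(ids))
  if (!is.null(matrix)) {
    stopifnot(inherits(matrix, "criteria_matrix"))
    st <- matrix$status[match(ids, matrix$record_ids)]
    processed <- !is.na(st) & st == "ok"
  }
  cm <- confusion(d[processed], truth[processed])
  list(confusion = cm,
       metrics = classification_metrics(cm),
       agreement = agreement_stats(cm),
       workload = workload_reduction(cm$tp + cm$tn, dataset$original_total),
       n_failed = sum(!processed))
}
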