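#' Assemble a records-by-criteria verdict matrix
#'
#' Collects the per-criterion Boolean verdicts of a screening run into a
#' complete logical matrix, the input to both decision rules. Records whose
#' judging failed get an all-`FALSE` row and status `"failed"` — a failed
#' record can never satisfy every criterion, so it flows into the residual
#' human workload rather than being silently included — while retaining the
#' failed status so evaluation can account for it separately.
#'
#' @param result A `screen_result` from [screen_corpus()] or
#'   [simulate_verdicts()].
#' @param criteria A [criteria_set()].
#' @param record_ids Row order; defaults to succeeded-then-missing order of
#'   `result`.
#' @return A `criteria_matrix`: list with `record_ids`, `criterion_keys`,
#'   `values` (logical matrix, no missing cells), and `status`
#'   (`"ok"`/`"failed"` per record).
#' @export
criteria_matrix <- function(result, criteria, record_ids = NULL) {
  stopifnot(inherits(result, "screen_result"), inherits(criteria, "criteria_set"))
  all_sets <- c(result$succeeded, result$missing)
  if (is.null(record_ids)) record_ids <- names(all_sets)
  missing_ids <- setdiff(record_ids, names(all_sets))
  if (length(missing_ids) > 0) {
    sf_stop("screenflow_alignment_error",
            "no verdicts for record(s): %s", paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  values <- matrix(FALSE, nrow = length(record_ids), ncol = nrow(criteria),
                   dimnames = list(record_ids, criteria$key))
  status <- stats::setNames(rep("failed", length(record_ids)), record_ids)
  for (id in record_ids) {
    vs <- all_sets[[id]]
    status[[id]] <- vs$status
    if (vs$status == "ok") {
      values[id, ] <- vapply(criteria$key, function(k) isTRUE(vs$verdicts[[k]]$value),
                             logical(1))
    }
  }
  new_criteria_matrix(record_ids, criteria$key, values, unname(status))
}

new_criteria_matrix <- function(record_ids, criterion_keys, values, status) {
  stopifnot(is.matrix(values), is.logical(values),
            nrow(values) == length(record_ids),
            ncol(values) == length(criterion_keys),
            length(status) == length(record_ids),
            !anyNA(values))
  dimnames(values) <- list(record_ids, criterion_keys)
  structure(list(record_ids = record_ids,
                 criterion_keys = criterion_keys,
                 values = values,
                 status = status),
            class = "criteria_matrix")
}

#' @export
print.criteria_matrix <- function(x, ...) {
  cat(sprintf("<criteria_matrix> %d records x %d criteria (%d failed)\n",
              length(x$record_ids), length(x$criterion_keys),
              sum(x$status == "failed")))
  invisible(x)
}

new_decision_vector <- function(record_ids, decision, rule) {
  structure(data.frame(record_id = record_ids, decision = decision,
                       stringsAsFactors = FALSE),
            rule = rule, class = c("decision_vector", "data.frame"))
}

#' Strict all-criteria-true decision rule
#'
#' A record is machine-included if and only if every criterion verdict in
#' its row is `TRUE`; any single false criterion excludes it. Records with
#' failed judging status decide `FALSE`. This is the stringent baseline
#' rule: it favours specificity over recall, since one missed criterion is
#' enough to exclude.
#'
#' @param matrix A `criteria_matrix`.
#' @return A `decision_vector` data frame (`record_id`, `decision`) with
#'   attribute `rule = "all_true"`.
#' @export
all_true_rule <- function(matrix) {
  stopifnot(inherits(matrix, "criteria_matrix"))
  if (length(matrix$criterion_keys) == 0) {
    sf_stop("screenflow_config_error",
            "all_true_rule over zero criteria would include everything vacuously")
  }
  if (length(matrix$record_ids) == 0) {
    sf_stop("screenflow_config_error", "empty criteria matrix")
  }
  decision <- rowSums(matrix$values) == ncol(matrix$values) & matrix$status == "ok"
  new_decision_vector(matrix$record_ids, unname(decision), "all_true")
}

#' Adaptive cross-validation fold count
#'
#' Chooses the number of stratified folds from the minority-class size:
#' five folds when the smaller class has at least five members, otherwise
#' as many folds as that class allows, never fewer than two. This keeps at
#' least one member of each class in every fold even for small, imbalanced
#' screening corpora.
#'
#' @param class_counts Integer vector of length 2: counts of the two
#'   classes (order irrelevant).
#' @return Integer fold count `k` with `2 <= k <= 5`.
#' @export
adaptive_fold_count <- function(class_counts) {
  stopifnot(length(class_counts) == 2)
  m <- min(class_counts)
  if (m < 2) {
    sf_stop("screenflow_class_error",
            "smallest class has %d member(s); at least 2 are required for cross-validation", m)
  }
  as.integer(min(5L, max(2L, m)))
}

# Stratified fold assignment: within each class, ids are shuffled and dealt
# round-robin, so per-class fold sizes differ by at most one.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Random-forest criterion combiner with out-of-fold predictions
#'
#' Trains random forests on the criterion verdicts to predict the human
#' screening-1 label, producing for every record an out-of-fold prediction:
#' the forest voting on a record never saw that record's fold during
#' training. Forests use 100 trees and class weights inversely proportional
#' to class frequencies (balanced), and the fold count adapts to the
#' minority-class size via [adaptive_fold_count()]. Unlike the strict
#' all-true rule, the forest learns the relative importance of each
#' criterion, so a record can be included despite one false criterion.
#'
#' Records with failed judging status are excluded from training and
#' receive decision `FALSE`, keeping them in the residual-workload pool.
#' Constant criterion columns trigger a warning but predictions are still
#' produced.
#'
#' @param matrix A `criteria_matrix`.
#' @param labels Logical vector of human screening-1 labels aligned with
#'   `matrix$record_ids`.
#' @param n_trees Number of trees per forest (default 100).
#' @param seed Integer seed; the same inputs and seed reproduce decisions
#'   exactly (default 28).
#' @param threshold Vote-fraction threshold for inclusion (default 0.5,
#'   majority vote).
#' @return A `decision_vector` with attribute `rule = "random_forest"` and
#'   attributes `k` (folds used) and `oof_prob` (out-of-fold inclusion
#'   vote fractions, `NA` for failed records).
#' @export
rf_out_of_fold <- function(matrix, labels, n_trees = 100L, seed = 28L,
                           threshold = 0.5) {
  stopifnot(inherits(matrix, "criteria_matrix"))
  n <- length(matrix$record_ids)
  if (length(labels) != n) {
    sf_stop("screenflow_alignment_error",
            "labels (%d) do not align with matrix rows (%d)", length(labels), n)
  }
  ok <- matrix$status == "ok"
  y <- factor(ifelse(labels[ok], "inc", "exc"), levels = c("exc", "inc"))
  counts <- table(y)
  if (any(counts == 0)) {
    sf_stop("screenflow_class_error", "both classes must be present among judged records")
  }
  k <- adaptive_fold_count(as.integer(counts))

  x <- matrix$values[ok, , drop = FALSE]
  storage.mode(x) <- "double"
  if (any(apply(x, 2, function(col) length(unique(col))) == 1)) {
    warning("criteria matrix has constant column(s); forest predictions may be uninformative")
  }
  x <- as.data.frame(x)

  # balanced class weights: n / (n_classes * n_c), as in inverse-frequency weighting
  n_ok <- sum(ok)
  classwt <- stats::setNames(n_ok / (2 * as.numeric(counts)), names(counts))

  prob_ok <- rep(NA_real_, n_ok)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  folds <- stratified_folds(as.character(y), k)
  for (f in seq_len(k)) {
    train <- folds != f
    fit <- randomForest::randomForest(
      x = x[train, , drop = FALSE], y = y[train],
      ntree = as.integer(n_trees), classwt = classwt[levels(y)]
    )
    prob_ok[!train] <- stats::predict(fit, x[!train, , drop = FALSE],
                                      type = "prob")[, "inc"]
  }

  prob <- rep(NA_real_, n)
  prob[ok] <- prob_ok
  decision <- rep(FALSE, n)
  decision[ok] <- prob_ok >= threshold
  out <- new_decision_vector(matrix$record_ids, decision, "random_forest")
  attr(out, "k") <- k
  attr(out, "oof_prob") <- prob
  out
}

#' Write a decision vector as CSV
#'
#' @param decisions A `decision_vector`.
#' @param path Output CSV path (columns `record_id`, `decision`, `rule`).
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  stopifnot(inherits(decisions, "decision_vector"))
  df <- data.frame(record_id = decisions$record_id,
                   decision = decisions$decision,
                   rule = attr(decisions, "rule"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
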