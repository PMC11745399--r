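# Independent oracles used to cross-check the package's evaluation code.
# They deliberately work from raw prediction/truth vectors (never from the
# package's confusion object) so the two routes share no code.

# Expand a confusion-cell specification into raw aligned logical vectors.
cells_to_vectors <- function(tp, fp, fn, tn) {
  list(
    pred  = c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, fn), rep(FALSE, tn)),
    truth = c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
  )
}

# Brute-force metric computation by explicit pair counting over raw vectors.
oracle_metrics <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1
    else if (pred[i] && !truth[i]) fp <- fp + 1
    else if (!pred[i] && truth[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  specificity <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  # MCC of two binary vectors is their Pearson correlation
  mcc <- suppressWarnings(stats::cor(as.numeric(pred), as.numeric(truth)))
  if (!is.na(mcc) && is.nan(mcc)) mcc <- NA_real_
  n <- length(pred)
  p0 <- mean(pred == truth)
  # chance agreement from marginal proportions, computed from the raw vectors
  pe <- mean(pred) * mean(truth) + mean(!pred) * mean(!truth)
  kappa <- if (pe == 1) NA_real_ else (p0 - pe) / (1 - pe)
  list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
       precision = precision, recall = recall, specificity = specificity,
       f1 = f1, mcc = mcc, p0 = p0, kappa = kappa, pabak = 2 * p0 - 1)
}

# Random confusion cells with at least one pair in total.
random_cells <- function() {
  repeat {
    cells <- stats::rpois(4, lambda = sample(1:40, 1))
    if (sum(cells) >= 1) return(cells)
  }
}

# Raw-row builder for the records module.
make_raw_rows <- function(title, abstract, screening1, screening2 = "unknown",
                          language = "", source_key = "") {
  data.frame(title = title, abstract = abstract,
             screening1 = screening1,
             screening2 = rep_len(screening2, length(title)),
             language = rep_len(language, length(title)),
             source_key = rep_len(source_key, length(title)),
             stringsAsFactors = FALSE)
}

# Two-criterion test criteria set reused across judge/decide tests.
toy_criteria <- function(keys = c("population", "outcome")) {
  criteria_set(keys, paste("Return true if the record satisfies", keys,
                           "for the review question; otherwise return false."))
}

# Small simulated corpus plus verdicts, a shared fixture for pipeline tests.
toy_simulation <- function(n = 60, prevalence = 0.3, s = 0.9, f = 0.1,
                           failure_rate = 0, seed = 28, n_criteria = 2) {
  keys <- paste0("crit", seq_len(n_criteria))
  profiles <- lapply(keys, criterion_profile, sensitivity = s,
                     false_positive_rate = f)
  cfg <- simulation_config(n, prevalence, profiles,
                           failure_rate = failure_rate, seed = seed)
  ds <- generate_review(cfg)
  sim <- simulate_verdicts(ds, cfg)
  list(cfg = cfg, dataset = ds, sim = sim, criteria = toy_criteria(keys))
}
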