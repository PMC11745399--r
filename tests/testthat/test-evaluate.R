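test_that("the confusion matrix counts exact agreement and disagreement pairs", {
  truth <- rep(c(TRUE, FALSE), 5)
  cm <- confusion(truth, truth)
  expect_equal(c(cm$fp, cm$fn), c(0, 0))
  expect_equal(cm$n, 10)
  anti <- confusion(!truth, truth)
  expect_equal(c(anti$tp, anti$tn), c(0, 0))
  expect_equal(c(anti$fp, anti$fn), c(5, 5))
})

test_that("confusion on 500 random pairs equals a four-way counting oracle", {
  set.seed(28)
  pred <- stats::runif(500) < 0.3
  truth <- stats::runif(500) < 0.1
  cm <- confusion(pred, truth)
  oracle <- oracle_metrics(pred, truth)
  expect_equal(cm$tp, oracle$tp)
  expect_equal(cm$fp, oracle$fp)
  expect_equal(cm$fn, oracle$fn)
  expect_equal(cm$tn, oracle$tn)
  expect_equal(cm$n, 500)
})

test_that("decision vectors align to truth by record id, and mismatches error", {
  values <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  cmat <- screenflow:::new_criteria_matrix(c("rec-00001", "rec-00002"),
                                           c("a", "b"), values, rep("ok", 2))
  dec <- all_true_rule(cmat)
  truth <- c("rec-00002" = TRUE, "rec-00001" = FALSE)  # reversed order
  cm <- confusion(dec, truth)
  expect_equal(cm$n, 2)
  expect_error(confusion(dec, c("rec-00001" = TRUE, "rec-00003" = FALSE)),
               class = "screenflow_alignment_error")
  expect_error(confusion(c(TRUE, FALSE), TRUE), class = "screenflow_alignment_error")
})

test_that("a perfect classifier scores one everywhere; a coin-flip table scores zero MCC", {
  perfect <- classification_metrics(confusion_from_counts(5, 0, 0, 5))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)

  symmetric <- classification_metrics(confusion_from_counts(1, 1, 1, 1))
  expect_equal(symmetric$mcc, 0)
  expect_equal(symmetric$f1, 0.5)
})

test_that("all five metrics match the independent oracle to 1e-12", {
  v <- cells_to_vectors(50, 5, 10, 100)
  m <- classification_metrics(confusion(v$pred, v$truth))
  o <- oracle_metrics(v$pred, v$truth)
  for (metric in c("precision", "recall", "specificity", "f1", "mcc")) {
    expect_equal(m[[metric]], o[[metric]], tolerance = 1e-12)
  }
})

test_that("zero denominators yield undefined flags, never errors or zeros", {
  all_neg <- classification_metrics(confusion_from_counts(0, 0, 0, 10))
  expect_true(is.na(all_neg$precision))
  expect_true(is.na(all_neg$recall))
  expect_equal(all_neg$specificity, 1)
  expect_true(is.na(all_neg$f1))
  expect_true(is.na(all_neg$mcc))
  # kappa undefined when both raters are constant and agree
  ag <- agreement_stats(confusion_from_counts(0, 0, 0, 10))
  expect_true(is.na(ag$kappa))
  expect_equal(ag$pabak, 1)
})

test_that("agreement statistics hit the stated PABAK anchor points", {
  chance <- agreement_stats(confusion_from_counts(25, 25, 25, 25))
  expect_equal(chance$p0, 0.5)
  expect_equal(chance$pabak, 0)

  perfect <- agreement_stats(confusion_from_counts(10, 0, 0, 10))
  expect_equal(perfect$p0, 1)
  expect_equal(perfect$pabak, 1)
  expect_equal(perfect$kappa, 1)

  mid <- agreement_stats(confusion_from_counts(40, 10, 10, 40))
  expect_equal(mid$p0, 0.8)
  expect_equal(mid$pabak, 0.6)
})

test_that("pabak = 2*p0 - 1 exactly on randomized confusion matrices", {
  set.seed(28)
  for (i in 1:200) {
    cells <- random_cells()
    cm <- confusion_from_counts(cells[1], cells[2], cells[3], cells[4])
    ag <- agreement_stats(cm)
    expect_identical(ag$pabak, 2 * ag$p0 - 1)
    expect_gte(ag$pabak, -1)
    expect_lte(ag$pabak, 1)
  }
})

test_that("kappa equals pabak when both marginals are balanced", {
  # prevalence index (tp - tn)/n = 0 and bias index (fp - fn)/n = 0
  for (cells in list(c(10, 5, 5, 10), c(3, 20, 20, 3), c(7, 7, 7, 7))) {
    ag <- agreement_stats(confusion_from_counts(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(ag$kappa, ag$pabak, tolerance = 1e-12)
  }
})

test_that("kappa matches the marginal-product oracle on random tables", {
  set.seed(12)
  for (i in 1:100) {
    cells <- random_cells()
    v <- cells_to_vectors(cells[1], cells[2], cells[3], cells[4])
    ag <- agreement_stats(confusion(v$pred, v$truth))
    o <- oracle_metrics(v$pred, v$truth)
    expect_equal(ag$p0, o$p0, tolerance = 1e-12)
    expect_equal(ag$kappa, o$kappa, tolerance = 1e-12)
  }
})

test_that("MCC is symmetric under simultaneous class swap", {
  set.seed(3)
  for (i in 1:50) {
    cells <- random_cells()
    m1 <- classification_metrics(confusion_from_counts(cells[1], cells[2], cells[3], cells[4]))
    m2 <- classification_metrics(confusion_from_counts(cells[4], cells[3], cells[2], cells[1]))
    expect_equal(m1$mcc, m2$mcc, tolerance = 1e-12)
  }
})

test_that("workload accounting reproduces the printed review arithmetic", {
  r1 <- workload_reduction(4294, 4662)
  expect_equal(r1$remaining, 368)
  expect_equal(r1$reduction_percent, 92)

  r2 <- workload_reduction(1539, 1741)
  expect_equal(r2$remaining, 202)
  expect_equal(r2$reduction_percent, 88)

  expect_equal(workload_reduction(4329, 4662)$reduction_percent, 93)
  expect_equal(workload_reduction(4130, 4662)$reduction_percent, 89)
  expect_equal(workload_reduction(0, 100)$reduction_percent, 0)
  expect_equal(workload_reduction(100, 100)$reduction_percent, 100)
})

test_that("workload conservation and bounds hold for arbitrary inputs", {
  set.seed(1)
  for (i in 1:100) {
    total <- sample(1:10000, 1)
    correct <- sample(0:total, 1)
    w <- workload_reduction(correct, total)
    expect_equal(w$remaining + w$correct, w$original_total)
    expect_gte(w$reduction_percent, 0)
    expect_lte(w$reduction_percent, 100)
  }
  expect_error(workload_reduction(11, 10), class = "screenflow_accounting_error")
  expect_error(workload_reduction(1, 0), class = "screenflow_config_error")
})

test_that("workload summaries expose both aggregation orders", {
  s <- summarize_workload(c(4130, 4294, 4329), 4662)
  expect_equal(s$min$reduction_percent, 89)
  expect_equal(s$max$reduction_percent, 93)
  expect_equal(s$mean$correct, 4251)
  expect_equal(s$mean$reduction_percent, 91)
  expect_equal(s$mean_of_percents, mean(c(89, 92, 93)))
})

test_that("criterion correlations recover perfect, inverted and independent columns", {
  set.seed(28)
  n <- 1000
  truth <- stats::runif(n) < 0.4
  values <- cbind(truth, !truth, stats::runif(n) < 0.5, rep(TRUE, n))
  cmat <- screenflow:::new_criteria_matrix(
    sprintf("rec-%05d", 1:n), c("same", "inverted", "noise", "constant"),
    values, rep("ok", n))
  cc <- criterion_correlations(cmat, truth)
  expect_equal(cc$criterion, sort(c("same", "inverted", "noise", "constant")))
  r <- stats::setNames(cc$r, cc$criterion)
  expect_equal(unname(r["same"]), 1)
  expect_equal(unname(r["inverted"]), -1)
  expect_lt(abs(r["noise"]), 0.1)
  expect_true(is.na(r["constant"]))
})

test_that("evaluate_run stitches all reports together consistently", {
  fx <- toy_simulation(n = 80, prevalence = 0.25, seed = 2)
  cmat <- fx$sim$matrix
  dec <- all_true_rule(cmat)
  ev <- evaluate_run(dec, fx$dataset)
  expect_equal(ev$confusion$n, 80)
  expect_equal(ev$workload$correct, ev$confusion$tp + ev$confusion$tn)
  expect_equal(ev$agreement$p0, ev$workload$correct / 80)
  expect_equal(ev$workload$original_total, fx$dataset$original_total)
})
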