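test_that("auroc matches the pairwise-concordance oracle and handles edge rankings", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.9), c(1, 0)), 0.0)
  expect_equal(auroc(c(0.5, 0.5, 0.5), c(1, 0, 1)), 0.5)
  for (seed in 1:5) {
    inst <- random_instance(200, seed)
    expect_equal(auroc(inst$scores, inst$labels),
                 auroc_oracle(inst$scores, inst$labels), tolerance = 1e-12)
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("average precision matches the threshold-enumeration oracle", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # single positive ranked last of n has AP 1/n
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 1 / 4)
  for (seed in 1:5) {
    inst <- random_instance(200, seed)
    expect_equal(average_precision(inst$scores, inst$labels),
                 ap_oracle(inst$scores, inst$labels), tolerance = 1e-12)
  }
  expect_error(average_precision(c(0.4, 0.2), c(0, 0)), "positive")
})

test_that("F1 threshold search is exhaustive-optimal and ties break low", {
  # perfectly separated scores reach F1 = 1
  sep <- best_f1_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$f1, 1.0)
  expect_lt(sep$threshold, 0.8)
  expect_gt(sep$threshold, 0.2)
  # all scores equal: best achievable F1 is the all-positive call, 2p/(p+1)
  n <- 10; pos <- 4; p <- pos / n
  eq <- best_f1_threshold(rep(0.5, n), c(rep(1, pos), rep(0, n - pos)))
  expect_equal(eq$f1, 2 * p / (p + 1))
  for (seed in 1:5) {
    inst <- random_instance(100, seed)
    expect_equal(best_f1_threshold(inst$scores, inst$labels)$f1,
                 best_f1_oracle(inst$scores, inst$labels), tolerance = 1e-12)
  }
})

test_that("fold-wise F1 selection averages confusion matrices over folds", {
  sc <- list(c(0.9, 0.8, 0.1), c(0.7, 0.3, 0.2))
  lb <- list(c(1, 1, 0), c(1, 0, 0))
  res <- f1_with_fold_threshold(sc, lb)
  expect_length(res$f1, 2)
  expect_equal(res$f1, c(1, 1))
  expect_equal(sum(res$mean_confusion), 3)  # both folds have 3 patients
})

test_that("paired fold test matches the textbook t statistic and is symmetric", {
  a <- c(0.80, 0.82, 0.85, 0.80, 0.81)
  b <- a - c(0.05, 0.06, 0.07, 0.05, 0.06)
  res <- paired_fold_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
  swapped <- paired_fold_test(b, a)
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$t, -res$t)
  # identical metrics: degenerate, flagged rather than p = 0
  dg <- paired_fold_test(a, a)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p_value))
})

test_that("metric report summarizes folds with ordered confidence intervals", {
  set.seed(11)
  sc <- lapply(1:4, function(i) runif(30))
  lb <- lapply(1:4, function(i) rbinom(30, 1, 0.4))
  rep1 <- metric_report(sc, lb)
  expect_s3_class(rep1, "bp_metric_report")
  expect_true(all(rep1$summary[, "lower"] <= rep1$summary[, "mean"]))
  expect_true(all(rep1$summary[, "mean"] <= rep1$summary[, "upper"]))
  expect_true(all(rep1$auroc >= 0 & rep1$auroc <= 1))
  # with a reference the paired tests appear
  rep2 <- metric_report(sc, lb, reference_scores_by_fold = sc)
  expect_true(rep2$paired$auroc$degenerate)
})

test_that("misclassification summary groups patients by outcome with exact quartiles", {
  pat <- toy_patients()
  scores <- data.frame(patient_id = pat$patient_id,
                       p_msi = c(0.9, 0.2, 0.1, 0.8, 0.3, 0.7, 0.1, 0.2))
  # threshold 0.5: P1 TP, P2 FN, P4 FP, P6 TP, others TN
  res <- misclassification_feature_summary(scores, pat, 0.5, level = "patient")
  expect_equal(res$n[res$outcome == "TP"], 2)
  expect_equal(res$n[res$outcome == "FN"], 1)
  expect_equal(res$n[res$outcome == "FP"], 1)
  expect_equal(res$n[res$outcome == "TN"], 4)
  tp_snp <- sort(c(1500, 90))
  expect_equal(res$snp_median[res$outcome == "TP"],
               unname(quantile(tp_snp, 0.5)))
  expect_equal(res$snp_q1[res$outcome == "TP"],
               unname(quantile(tp_snp, 0.25)))
  expect_equal(res$snp_median[res$outcome == "FN"], 1200)
  expect_equal(res$cimp_CIMP_H[res$outcome == "TP"], 2)
  # all predictions correct leaves FP and FN empty
  perfect <- data.frame(patient_id = pat$patient_id,
                        p_msi = ifelse(pat$subtype == "MSI", 0.9, 0.1))
  res2 <- misclassification_feature_summary(perfect, pat, 0.5, level = "patient")
  expect_equal(res2$n[res2$outcome %in% c("FP", "FN")], c(0, 0))
})

test_that("curve points reproduce the trapezoidal AUROC", {
  inst <- random_instance(150, 99)
  pts <- curve_points(inst$scores, inst$labels, "roc")
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(trap, auroc(inst$scores, inst$labels), tolerance = 1e-12)
})
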