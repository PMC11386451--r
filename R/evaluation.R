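# Patient-level performance metrics with fold-wise statistics.
#
# MSI is the positive class throughout; MSS is the negative class.

# Normalize labels to 0/1 with MSI (or TRUE/1) as the positive class.
as_binary_label <- function(labels, positive = "MSI") {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    out <- as.integer(labels == positive)
  } else {
    out <- as.integer(labels != 0)
  }
  if (anyNA(out)) stop_input("labels contain missing values")
  out
}

#' Area under the ROC curve
#'
#' Computes the probability that a randomly chosen positive (MSI) patient
#' outranks a randomly chosen negative (MSS) patient, with tied scores
#' counted one half. This rank-based form equals the trapezoidal area under
#' the ROC curve.
#'
#' @param scores Numeric vector of predicted MSI scores.
#' @param labels Class labels: `"MSI"`/`"MSS"` strings, a factor, or 0/1
#'   with 1 = MSI.
#' @param positive Label value treated as the positive class.
#' @return A single number in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c("MSI", "MSI", "MSS", "MSS"))
#' @export
auroc <- function(scores, labels, positive = "MSI") {
  y <- as_binary_label(labels, positive)
  if (length(scores) != length(y)) stop_input("scores and labels differ in length")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop_input("auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area beneath the precision-recall curve)
#'
#' Step-wise average precision: the sum over descending unique score
#' thresholds of the recall increment times the precision at that threshold.
#'
#' @inheritParams auroc
#' @return A single number in \[0, 1\].
#' @export
average_precision <- function(scores, labels, positive = "MSI") {
  y <- as_binary_label(labels, positive)
  if (length(scores) != length(y)) stop_input("scores and labels differ in length")
  n_pos <- sum(y == 1)
  if (n_pos == 0) stop_input("average_precision needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate only at the last occurrence of each unique score (threshold set)
  last <- !duplicated(s, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

f1_score <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Confusion matrix at a score threshold
#'
#' Patients with `score > threshold` are called MSI (positive).
#'
#' @inheritParams auroc
#' @param threshold Decision threshold on the MSI score.
#' @return A 2x2 integer matrix with rows = reference (MSI, MSS) and
#'   columns = call (MSI, MSS).
#' @export
confusion_at <- function(scores, labels, threshold, positive = "MSI") {
  y <- as_binary_label(labels, positive)
  call_pos <- scores > threshold
  m <- matrix(c(sum(y == 1 & call_pos), sum(y == 1 & !call_pos),
                sum(y == 0 & call_pos), sum(y == 0 & !call_pos)),
              nrow = 2, byrow = TRUE,
              dimnames = list(reference = c("MSI", "MSS"),
                              call = c("MSI", "MSS")))
  m
}

#' F1-maximizing threshold for one fold
#'
#' Sweeps every midpoint between adjacent sorted unique scores, plus 0 and 1,
#' and returns the threshold with the highest F1 for calling MSI when
#' `score > threshold`. Ties are broken toward the lower threshold.
#'
#' @inheritParams auroc
#' @return A list with `threshold`, `f1`, and the `confusion` matrix at the
#'   selected threshold.
#' @export
best_f1_threshold <- function(scores, labels, positive = "MSI") {
  y <- as_binary_label(labels, positive)
  if (all(y == 1) || all(y == 0)) stop_input("best_f1_threshold needs both classes")
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                        u[1] - .Machine$double.eps)))
  f1s <- vapply(cand, function(th) {
    cp <- scores > th
    f1_score(sum(y == 1 & cp), sum(y == 0 & cp), sum(y == 1 & !cp))
  }, numeric(1))
  best <- which.max(f1s)  # which.max takes the first (lowest) on ties
  list(threshold = cand[best], f1 = f1s[best],
       confusion = confusion_at(scores, y, cand[best], positive = 1))
}

#' Fold-wise F1 with per-fold threshold selection
#'
#' For each fold, selects the F1-maximizing threshold on that fold's scores
#' and reports the per-fold F1 values together with the element-wise average
#' of the per-fold confusion matrices.
#'
#' @param scores_by_fold List of numeric score vectors, one per fold.
#' @param labels_by_fold List of label vectors matching `scores_by_fold`.
#' @param positive Label value treated as positive.
#' @return A list with `f1` (per fold), `threshold` (per fold), and
#'   `mean_confusion` (2x2 averaged counts).
#' @export
f1_with_fold_threshold <- function(scores_by_fold, labels_by_fold,
                                   positive = "MSI") {
  stopifnot(length(scores_by_fold) == length(labels_by_fold))
  picks <- Map(best_f1_threshold, scores_by_fold, labels_by_fold,
               MoreArgs = list(positive = positive))
  conf <- Reduce(`+`, lapply(picks, `[[`, "confusion")) / length(picks)
  list(f1 = vapply(picks, `[[`, numeric(1), "f1"),
       threshold = vapply(picks, `[[`, numeric(1), "threshold"),
       mean_confusion = conf)
}

#' Paired t-test across cross-validation folds
#'
#' Two-sided Student's paired t-test on per-fold metric differences between
#' two models evaluated on the same folds. A zero-variance difference vector
#' leaves the p-value undefined; this is flagged rather than reported as a
#' numeric p.
#'
#' @param metric_a,metric_b Numeric vectors of per-fold metric values.
#' @return A list with `t`, `p_value`, `mean_diff`, and `degenerate`
#'   (`TRUE` when the difference has zero variance and p is undefined).
#' @export
paired_fold_test <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stop_input("fold metric vectors differ in length")
  if (length(metric_a) < 2) stop_input("paired test needs at least 2 folds")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p_value = NA_real_, mean_diff = mean(d),
                degenerate = TRUE))
  }
  ht <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value, mean_diff = mean(d),
       degenerate = FALSE)
}

# mean and normal-approximation 95% CI across folds; also a percentile option
fold_ci <- function(x, level = 0.95, method = c("normal", "percentile")) {
  method <- match.arg(method)
  m <- mean(x)
  if (method == "normal") {
    half <- stats::qnorm(1 - (1 - level) / 2) * stats::sd(x) / sqrt(length(x))
    c(mean = m, lower = m - half, upper = m + half)
  } else {
    q <- stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    c(mean = m, lower = q[1], upper = q[2])
  }
}

#' Fold-wise metric report for patient-level MSI scoring
#'
#' Computes AUROC, average precision, and F1 (with per-fold threshold
#' selection) for a set of cross-validation folds, with means, standard
#' deviations, and 95% confidence intervals across folds, and optionally a
#' paired t-test against a reference model evaluated on the same folds.
#'
#' @param scores_by_fold List of per-fold numeric MSI score vectors.
#' @param labels_by_fold List of per-fold label vectors.
#' @param reference_scores_by_fold Optional list of per-fold scores from a
#'   reference model (same folds and labels) for the paired test.
#' @param ci_method `"normal"` (mean +/- 1.96 sd/sqrt(k)) or `"percentile"`.
#' @return An object of class `bp_metric_report`: per-fold metric vectors,
#'   summary rows (mean, sd, CI), the averaged confusion matrix at the
#'   per-fold F1 thresholds, and (if a reference is given) paired-test
#'   results per metric.
#' @export
metric_report <- function(scores_by_fold, labels_by_fold,
                          reference_scores_by_fold = NULL,
                          ci_method = c("normal", "percentile")) {
  ci_method <- match.arg(ci_method)
  k <- length(scores_by_fold)
  stopifnot(k == length(labels_by_fold))
  auc <- mapply(auroc, scores_by_fold, labels_by_fold)
  ap <- mapply(average_precision, scores_by_fold, labels_by_fold)
  f1 <- f1_with_fold_threshold(scores_by_fold, labels_by_fold)
  summarize <- function(x) {
    ci <- fold_ci(x, method = ci_method)
    c(ci["mean"], sd = stats::sd(x), ci["lower"], ci["upper"])
  }
  out <- list(
    k = k,
    auroc = auc, ap = ap, f1 = f1$f1,
    f1_threshold = f1$threshold,
    mean_confusion = f1$mean_confusion,
    summary = rbind(auroc = summarize(auc), ap = summarize(ap),
                    f1 = summarize(f1$f1)),
    ci_method = ci_method
  )
  if (!is.null(reference_scores_by_fold)) {
    ref_auc <- mapply(auroc, reference_scores_by_fold, labels_by_fold)
    ref_ap <- mapply(average_precision, reference_scores_by_fold, labels_by_fold)
    ref_f1 <- f1_with_fold_threshold(reference_scores_by_fold, labels_by_fold)$f1
    out$paired <- list(auroc = paired_fold_test(auc, ref_auc),
                       ap = paired_fold_test(ap, ref_ap),
                       f1 = paired_fold_test(f1$f1, ref_f1))
    out$reference <- list(auroc = ref_auc, ap = ref_ap, f1 = ref_f1)
  }
  class(out) <- "bp_metric_report"
  out
}

#' @export
print.bp_metric_report <- function(x, ...) {
  cat(sprintf("Patient-level metric report over %d folds (MSI positive)\n", x$k))
  s <- x$summary
  for (m in rownames(s)) {
    cat(sprintf("  %-5s %.3f +/- %.3f (95%% CI %.3f-%.3f)\n",
                m, s[m, "mean"], s[m, "sd"], s[m, "lower"], s[m, "upper"]))
  }
  if (!is.null(x$paired)) {
    p <- x$paired$auroc
    cat(sprintf("  paired t-test vs reference (AUROC): mean diff %+.3f, p = %s\n",
                p$mean_diff,
                if (isTRUE(p$degenerate)) "undefined (zero-variance)" else
                  format.pval(p$p_value, digits = 3)))
  }
  invisible(x)
}

#' Molecular-feature summary of classification outcomes
#'
#' Cross-tabulates classification outcome (TP / FP / TN / FN at a given MSI
#' score threshold, MSI positive) against patient-level molecular features:
#' quartiles of SNP count and CNV fraction, and counts of CIMP categories.
#' Works at patch level (each patch called from its own score, features
#' inherited from its patient) or at patient level.
#'
#' @param scores Data frame with `patient_id` and a score column: `p_msi`
#'   for patient level, or `patch_id` + `p_msi` for patch level.
#' @param patients Patient table with `patient_id`, `subtype`, `snp_count`,
#'   `cimp_category`, `cnv_fraction`.
#' @param threshold MSI call threshold (`score > threshold` calls MSI).
#' @param level `"patch"` or `"patient"` granularity.
#' @return A data frame with one row per outcome cell (TP, FN, FP, TN):
#'   group size, quartiles of `snp_count` and `cnv_fraction`, and one count
#'   column per CIMP category. Records whose patient lacks a feature value
#'   are counted in `n_missing_features` rather than dropped silently.
#' @export
misclassification_feature_summary <- function(scores, patients, threshold,
                                              level = c("patch", "patient")) {
  level <- match.arg(level)
  check_columns(scores, c("patient_id", "p_msi"), "scores")
  check_columns(patients, c("patient_id", "subtype", "snp_count",
                            "cimp_category", "cnv_fraction"), "patients")
  idx <- match(scores$patient_id, patients$patient_id)
  if (anyNA(idx)) stop_input("scores reference unknown patient_id(s)")
  if (level == "patient" && anyDuplicated(scores$patient_id)) {
    stop_input("patient-level summary requires one score row per patient")
  }
  y <- patients$subtype[idx] == "MSI"
  call_pos <- scores$p_msi > threshold
  outcome <- ifelse(y & call_pos, "TP", ifelse(y & !call_pos, "FN",
                    ifelse(!y & call_pos, "FP", "TN")))
  cimp_levels <- sort(unique(patients$cimp_category))
  cells <- c("TP", "FN", "FP", "TN")
  rows <- lapply(cells, function(cell) {
    sel <- outcome == cell
    snp <- patients$snp_count[idx][sel]
    cnv <- patients$cnv_fraction[idx][sel]
    cimp <- patients$cimp_category[idx][sel]
    n_missing <- sum(is.na(snp) | is.na(cnv) | is.na(cimp))
    qs <- function(v) if (all(is.na(v)) || !length(v)) rep(NA_real_, 3) else
      stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    snp_q <- qs(snp); cnv_q <- qs(cnv)
    counts <- vapply(cimp_levels, function(l) sum(cimp == l, na.rm = TRUE),
                     integer(1))
    out <- data.frame(outcome = cell, n = sum(sel),
                      n_missing_features = n_missing,
                      snp_q1 = snp_q[1], snp_median = snp_q[2], snp_q3 = snp_q[3],
                      cnv_q1 = cnv_q[1], cnv_median = cnv_q[2], cnv_q3 = cnv_q[3],
                      stringsAsFactors = FALSE)
    for (l in cimp_levels) out[[paste0("cimp_", gsub("[^A-Za-z0-9]", "_", l))]] <-
      counts[[l]]
    out
  })
  do.call(rbind, rows)
}

#' ROC and precision-recall curve points
#'
#' Returns the operating points of the ROC or PR curve for plotting.
#'
#' @inheritParams auroc
#' @param curve `"roc"` or `"pr"`.
#' @return A data frame of curve coordinates (`fpr`/`tpr` or
#'   `recall`/`precision`) in threshold-descending order.
#' @export
curve_points <- function(scores, labels, curve = c("roc", "pr"),
                         positive = "MSI") {
  curve <- match.arg(curve)
  y <- as_binary_label(labels, positive)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  n_pos <- sum(y); n_neg <- length(y) - n_pos
  if (curve == "roc") {
    data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  } else {
    data.frame(recall = tp / n_pos, precision = tp / (tp + fp))
  }
}
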