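# Class-decomposition schemes: split the MSI class into two genomically
# defined sub-classes while leaving MSS untouched.

#' Define a sub-labeling scheme
#'
#' A scheme maps each patient's subtype plus one genomic feature to a
#' training sub-label. Threshold schemes (SNP count, CNV fraction) send MSI
#' patients with a feature value strictly above the threshold to the high
#' sub-class and all others to the low sub-class; MSS patients keep the MSS
#' label. The CIMP scheme is categorical: MSI & CIMP-H form one sub-class,
#' all other MSI patients the second, and (for training only) MSS patients
#' with CIMP-H status are excluded, reflecting how rare CIMP-H is among MSS.
#'
#' Default thresholds: 1200 SNPs for `"snp"` (the value selected by a
#' validation sweep over the 800-1500 grid) and 0.005 for `"cnv"`.
#'
#' @param feature `"snp"`, `"cimp"`, or `"cnv"`.
#' @param threshold Threshold for threshold-rule features. Ignored for
#'   `"cimp"`.
#' @param exclude_mss_cimp_h For the CIMP scheme, whether to drop CIMP-H MSS
#'   patients from training sets (never from test data).
#' @return An object of class `bp_sublabel_scheme`.
#' @examples
#' sublabel_scheme("snp", threshold = 1200)
#' sublabel_scheme("cimp")
#' @export
sublabel_scheme <- function(feature = c("snp", "cimp", "cnv"),
                            threshold = NULL,
                            exclude_mss_cimp_h = (feature == "cimp")) {
  feature <- match.arg(feature)
  rule_kind <- if (feature == "cimp") "category" else "threshold"
  if (rule_kind == "threshold") {
    threshold <- threshold %||% switch(feature, snp = 1200, cnv = 0.005)
    if (!is.finite(threshold)) stop_input("threshold must be finite")
    classes <- c(low = "MSI1", high = "MSI2")
  } else {
    threshold <- NULL
    classes <- c(low = "MSI-NON-CIMP-H", high = "MSI-CIMP-H")
  }
  structure(list(feature = feature, rule_kind = rule_kind,
                 threshold = threshold,
                 low_class = unname(classes["low"]),
                 high_class = unname(classes["high"]),
                 exclude_mss_cimp_h = isTRUE(exclude_mss_cimp_h) &&
                   feature == "cimp"),
            class = "bp_sublabel_scheme")
}

#' @export
print.bp_sublabel_scheme <- function(x, ...) {
  if (x$rule_kind == "threshold") {
    cat(sprintf("Sub-label scheme: %s > %g -> %s, otherwise %s (MSS unchanged)\n",
                x$feature, x$threshold, x$high_class, x$low_class))
  } else {
    cat(sprintf("Sub-label scheme: CIMP-H -> %s, other MSI -> %s (MSS unchanged)%s\n",
                x$high_class, x$low_class,
                if (x$exclude_mss_cimp_h) "; CIMP-H MSS excluded from training" else ""))
  }
  invisible(x)
}

scheme_feature_values <- function(patients, scheme) {
  col <- switch(scheme$feature, snp = "snp_count", cnv = "cnv_fraction",
                cimp = "cimp_category")
  check_columns(patients, c("patient_id", "subtype", col), "patients")
  patients[[col]]
}

#' Assign training sub-labels to patients
#'
#' Applies a [sublabel_scheme()] to a patient table. MSS patients keep the
#' `MSS` label. MSI patients with feature value strictly greater than the
#' threshold receive the high sub-class; those at or below it the low
#' sub-class. For the categorical CIMP scheme, MSI & CIMP-H patients form
#' the high sub-class and all other MSI patients the low one.
#'
#' Collapsing the two MSI sub-classes back to MSI reproduces the original
#' binary labels exactly: the decomposition is a partition refinement.
#'
#' @param patients Patient table with `patient_id`, `subtype`, and the
#'   scheme's feature column (`snp_count`, `cimp_category`, or
#'   `cnv_fraction`).
#' @param scheme A [sublabel_scheme()].
#' @return A data frame with columns `patient_id` and `sub_label`.
#' @export
assign_sublabels <- function(patients, scheme) {
  stopifnot(inherits(scheme, "bp_sublabel_scheme"))
  vals <- scheme_feature_values(patients, scheme)
  is_msi <- patients$subtype == "MSI"
  missing_msi <- is_msi & is.na(vals)
  if (any(missing_msi)) {
    stop_input("MSI patient(s) missing %s value: %s", scheme$feature,
               paste(patients$patient_id[missing_msi], collapse = ", "))
  }
  high <- if (scheme$rule_kind == "threshold") {
    vals > scheme$threshold
  } else {
    vals == "CIMP-H"
  }
  sub <- ifelse(!is_msi, "MSS",
                ifelse(high, scheme$high_class, scheme$low_class))
  data.frame(patient_id = patients$patient_id, sub_label = sub,
             stringsAsFactors = FALSE)
}

#' Apply a scheme's training-set exclusion rule
#'
#' For schemes carrying an exclusion rule (the CIMP scheme by default),
#' removes CIMP-H MSS patients from the *training* split. Test patients and
#' MSI patients are always retained. Schemes without an exclusion rule
#' return the input unchanged.
#'
#' @param patients Patient table with `patient_id`, `subtype`, `split`, and
#'   `cimp_category`.
#' @inheritParams assign_sublabels
#' @return The filtered patient table.
#' @export
apply_training_exclusion <- function(patients, scheme) {
  stopifnot(inherits(scheme, "bp_sublabel_scheme"))
  if (!isTRUE(scheme$exclude_mss_cimp_h)) return(patients)
  check_columns(patients, c("patient_id", "subtype", "split", "cimp_category"),
                "patients")
  drop <- patients$split == "train" & patients$subtype == "MSS" &
    patients$cimp_category == "CIMP-H"
  patients[!drop, , drop = FALSE]
}

#' Select a sub-labeling threshold by validation AUROC
#'
#' Evaluates each candidate threshold by relabeling the training patients,
#' invoking a caller-supplied trainer, and recording the patient-level
#' validation AUROC; the candidate with the highest AUROC is selected, with
#' ties broken toward the smallest threshold. Candidates that leave either
#' MSI sub-class empty in the training patients are skipped with a warning.
#'
#' The default candidate grid for the SNP feature spans 800 to 1500 in
#' steps of 100.
#'
#' @param candidates Numeric vector of candidate thresholds.
#' @param train_patients,val_patients Patient tables for the training and
#'   validation folds (validation must contain both MSI and MSS patients).
#' @param trainer Function `(train_patients, val_patients, scheme) ->
#'   numeric` returning the patient-level validation AUROC of a model
#'   trained under that scheme.
#' @param feature Threshold-rule feature, `"snp"` or `"cnv"`.
#' @return An object of class `bp_sweep_result` with `candidates`,
#'   `val_auroc` (NA for skipped candidates), and `selected_threshold`.
#' @export
sweep_threshold <- function(candidates = seq(800, 1500, by = 100),
                            train_patients, val_patients, trainer,
                            feature = c("snp", "cnv")) {
  feature <- match.arg(feature)
  if (!length(candidates)) stop_input("no candidate thresholds supplied")
  if (!all(c("MSI", "MSS") %in% val_patients$subtype)) {
    stop_input("validation fold must contain both classes")
  }
  candidates <- sort(candidates)
  aucs <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    scheme <- sublabel_scheme(feature, threshold = candidates[i])
    subs <- assign_sublabels(train_patients, scheme)
    tab <- table(subs$sub_label)
    if (!all(c(scheme$low_class, scheme$high_class) %in% names(tab))) {
      warning(sprintf("threshold %g leaves an empty MSI sub-class; skipped",
                      candidates[i]), call. = FALSE)
      next
    }
    aucs[i] <- trainer(train_patients, val_patients, scheme)
  }
  if (all(is.na(aucs))) stop_input("every candidate threshold was invalid")
  best <- which.max(aucs)  # first max = smallest threshold on ties
  structure(list(candidates = candidates, val_auroc = aucs,
                 selected_threshold = candidates[best]),
            class = "bp_sweep_result")
}

#' @export
print.bp_sweep_result <- function(x, ...) {
  cat("Threshold sweep (validation patient-level AUROC):\n")
  print(data.frame(threshold = x$candidates, val_auroc = round(x$val_auroc, 4)))
  cat(sprintf("Selected threshold: %g\n", x$selected_threshold))
  invisible(x)
}
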