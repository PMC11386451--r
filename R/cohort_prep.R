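# Training-set preparation: patch-level class balancing, stratified
# patient-level folds, and weighted-sampler weights.

#' Balance patch counts across the two base classes
#'
#' Randomly discards patches of the majority base class until both classes
#' have equal patch counts. Every minority-class patch is retained. The rule
#' is symmetric: whichever class is larger is thinned.
#'
#' @param patches Patch table with a `base_label` column (`"MSI"`/`"MSS"`),
#'   or any two-level label column named by `label_col`.
#' @param seed Seed for the random discard (fixed seed gives a deterministic
#'   result).
#' @param label_col Name of the label column.
#' @return The balanced patch table (original row order preserved).
#' @export
balance_patches <- function(patches, seed = 1, label_col = "base_label") {
  check_columns(patches, label_col, "patches")
  lab <- patches[[label_col]]
  tab <- table(lab)
  if (length(tab) < 2) stop_input("balance_patches needs both classes present")
  if (length(tab) > 2) stop_input("balance_patches expects exactly two classes")
  if (tab[1] == tab[2]) return(patches)
  majority <- names(tab)[which.max(tab)]
  target <- min(tab)
  maj_idx <- which(lab == majority)
  keep_maj <- with_seed(sub_seed(seed, "balance"),
                        sample(maj_idx, target))
  keep <- sort(c(which(lab != majority), keep_maj))
  patches[keep, , drop = FALSE]
}

#' Stratified patient-level cross-validation folds
#'
#' Partitions patients into `k` folds stratified on a label (typically the
#' training sub-label), so that each fold's class composition differs from
#' the global proportions by at most one patient per stratum. Strata smaller
#' than `k` are distributed round-robin. The assignment depends only on the
#' seed and the set of patients, not on input row order.
#'
#' @param patients Patient table with `patient_id`.
#' @param strat_labels Vector of stratification labels, one per patient row,
#'   or the name of a column in `patients`.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return A data frame with `patient_id` and `fold` (0-based fold index),
#'   of class `bp_fold_assignment`.
#' @export
stratified_folds <- function(patients, strat_labels = "sub_label", k = 5,
                             seed = 1) {
  check_columns(patients, "patient_id", "patients")
  if (length(strat_labels) == 1 && is.character(strat_labels) &&
      strat_labels %in% names(patients)) {
    strat_labels <- patients[[strat_labels]]
  }
  if (length(strat_labels) != nrow(patients)) {
    stop_input("strat_labels must match the number of patients")
  }
  if (k < 2) stop_input("k must be at least 2")
  if (k > nrow(patients)) stop_input("k exceeds the number of patients")
  if (anyDuplicated(patients$patient_id)) stop_input("duplicate patient_id")
  # order-invariance: work on patients sorted by id
  ord <- order(patients$patient_id)
  ids <- patients$patient_id[ord]
  labs <- as.character(strat_labels)[ord]
  fold <- integer(length(ids))
  offset <- 0L  # rotate small-stratum round-robin start across strata
  for (s in sort(unique(labs))) {
    idx <- which(labs == s)
    perm <- with_seed(sub_seed(seed, paste0("folds:", s)),
                      sample(idx))
    fold[perm] <- (seq_along(perm) - 1L + offset) %% k
    offset <- (offset + length(perm)) %% k
  }
  structure(data.frame(patient_id = ids, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("bp_fold_assignment", "data.frame"))
}

#' Weighted-sampler weights for class-balanced batches
#'
#' Computes per-record sampling weights equal to the reciprocal of the
#' record's class count, so that sampling with replacement yields equal
#' expected class frequencies. Works for the binary base labels or the
#' three-class sub-labels alike.
#'
#' @param labels Vector of class labels, one per record.
#' @return Numeric weight vector aligned with `labels`.
#' @examples
#' sampling_weights(c("MSS", "MSS", "MSI1", "MSI2"))
#' @export
sampling_weights <- function(labels) {
  if (!length(labels)) stop_input("no labels supplied")
  tab <- table(labels)
  if (any(tab == 0)) stop_input("empty class in labels")
  unname(1 / as.numeric(tab[as.character(labels)]))
}
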