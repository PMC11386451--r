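# Patch-to-patient aggregation and probability-level fusion of two
# sub-class models.

msi_class_columns <- function(class_names) {
  msi <- setdiff(class_names, "MSS")
  if (!"MSS" %in% class_names || !length(msi) %in% c(1L, 2L)) {
    stop_input("unknown class layout: %s", paste(class_names, collapse = ", "))
  }
  msi
}

prediction_class_names <- function(preds) {
  setdiff(names(preds), c("patch_id", "patient_id"))
}

check_prediction_table <- function(preds, tol = 1e-6) {
  check_columns(preds, c("patch_id", "patient_id"), "prediction table")
  cls <- prediction_class_names(preds)
  P <- as.matrix(preds[cls])
  if (any(P < -tol | P > 1 + tol)) stop_input("probabilities outside [0, 1]")
  if (any(abs(rowSums(P) - 1) > tol)) {
    stop_input("probability rows do not sum to 1")
  }
  invisible(cls)
}

#' Per-patch MSI probability
#'
#' Collapses a patch's class-probability row to a single MSI probability.
#' For a binary model this is the MSI column itself; for a three-class
#' sub-class model it is the maximum of the two MSI sub-class
#' probabilities, taken per patch *before* any patient-level averaging.
#'
#' @param preds Prediction table: `patch_id`, `patient_id`, and one
#'   probability column per class (one of them `MSS`).
#' @return Numeric vector of per-patch MSI probabilities, aligned with the
#'   rows of `preds`.
#' @examples
#' p <- data.frame(patch_id = "p1", patient_id = "w1",
#'                 MSS = 0.2, MSI1 = 0.3, MSI2 = 0.5)
#' patch_msi_probability(p)  # 0.5
#' @export
patch_msi_probability <- function(preds) {
  cls <- check_prediction_table(preds)
  msi <- msi_class_columns(cls)
  if (length(msi) == 1) preds[[msi]] else pmax(preds[[msi[1]]], preds[[msi[2]]])
}

#' Patient-level MSI scores by patch averaging
#'
#' Computes each patient's MSI score as the arithmetic mean of their
#' patches' MSI probabilities (for three-class models, the per-patch
#' max-over-subclass rule is applied first). The score is
#' permutation-invariant and bounded by the patch probabilities' range.
#'
#' @inheritParams patch_msi_probability
#' @return A data frame with `patient_id` and `p_msi`, one row per patient.
#' @export
aggregate_patients <- function(preds) {
  check_prediction_table(preds)
  if (!nrow(preds)) stop_input("no patches to aggregate")
  p <- patch_msi_probability(preds)
  agg <- tapply(p, preds$patient_id, mean)
  data.frame(patient_id = names(agg), p_msi = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

align_prediction_pair <- function(preds_a, preds_b) {
  cls_a <- check_prediction_table(preds_a)
  cls_b <- check_prediction_table(preds_b)
  if (length(cls_a) != 3 || length(cls_b) != 3) {
    stop_input("fusion expects two three-class prediction tables")
  }
  only_a <- setdiff(preds_a$patch_id, preds_b$patch_id)
  only_b <- setdiff(preds_b$patch_id, preds_a$patch_id)
  if (length(only_a) || length(only_b)) {
    stop_input("patch sets differ; only in A: {%s}; only in B: {%s}",
               paste(utils::head(only_a, 5), collapse = ", "),
               paste(utils::head(only_b, 5), collapse = ", "))
  }
  b_idx <- match(preds_a$patch_id, preds_b$patch_id)
  X <- cbind(as.matrix(preds_a[cls_a]), as.matrix(preds_b[cls_b])[b_idx, ])
  list(X = X, patch_id = preds_a$patch_id, patient_id = preds_a$patient_id)
}

#' Train the probability-fusion perceptron
#'
#' Trains a small multi-layer perceptron that maps the concatenated
#' six-dimensional probability vector of two fixed three-class sub-class
#' models to a binary MSS/MSI probability. The constituent models are never
#' updated; only their output probabilities are consumed. Inputs are
#' aligned by `patch_id`, so row order is irrelevant.
#'
#' @param preds_a,preds_b Three-class prediction tables from the two
#'   constituent models, covering identical patch sets.
#' @param labels Binary patch labels: either a vector aligned with
#'   `preds_a` rows or a data frame with `patch_id` and `base_label`.
#' @param hidden_units Width of the single hidden layer.
#' @param epochs,learning_rate,batch_size Optimization settings for the
#'   Adam cross-entropy loop. The combiner must be trained to convergence:
#'   an underfit combiner down-weights the sub-class whose signal is weak
#'   at patch level but decisive after patient averaging.
#' @param balance_labels Optional class labels (vector aligned with
#'   `preds_a`, or data frame `patch_id`, `label`) used for the weighted
#'   sampler; supply the first constituent's sub-labels so the rare MSI
#'   sub-class keeps its sampling share. Defaults to the binary `labels`.
#' @param val_groups Optional grouping vector (aligned with `preds_a`, or
#'   data frame `patch_id`, `group`). When given, after each epoch the
#'   patient-level AUROC is computed within each group and averaged, and
#'   the best epoch's weights are kept. Use the constituent's fold index
#'   when training on out-of-fold predictions, so model selection is not
#'   confounded by calibration differences between fold models.
#' @param seed RNG seed (fixed seed gives identical weights and outputs).
#' @return An object of class `bp_fusion_model`.
#' @export
train_fusion <- function(preds_a, preds_b, labels, hidden_units = 16,
                         epochs = 300, learning_rate = 1e-3, batch_size = 64,
                         balance_labels = NULL, val_groups = NULL, seed = 1) {
  al <- align_prediction_pair(preds_a, preds_b)
  aligned <- function(x, col, what) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) {
      check_columns(x, c("patch_id", col), what)
      out <- x[[col]][match(al$patch_id, x$patch_id)]
    } else {
      if (length(x) != nrow(preds_a)) stop_input("%s length mismatch", what)
      out <- x
    }
    if (anyNA(out)) stop_input("%s missing for some patches", what)
    out
  }
  lab <- aligned(if (is.data.frame(labels)) {
    names(labels)[names(labels) == "base_label"] <- "label"
    labels
  } else labels, "label", "labels")
  y <- as_binary_label(lab) + 1L  # 1 = MSS, 2 = MSI
  if (length(unique(y)) < 2) stop_input("fusion training needs both classes")
  bal <- aligned(balance_labels, "label", "balance_labels") %||% y
  grp <- aligned(val_groups, "group", "val_groups")
  callback <- if (!is.null(grp)) {
    pid <- al$patient_id
    function(params) {
      P <- mlp_forward(params, al$X)
      aucs <- vapply(unique(grp), function(g) {
        sel <- grp == g
        sc <- tapply(P[sel, 2], pid[sel], mean)
        lb <- tapply(y[sel] == 2, pid[sel], function(z) z[1])
        if (length(unique(lb)) < 2) return(NA_real_)
        auroc(as.numeric(sc), as.integer(lb), positive = 1)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }
  } else NULL
  net <- mlp_train(al$X, y, n_classes = 2, hidden_units = hidden_units,
                   epochs = epochs, learning_rate = learning_rate,
                   batch_size = batch_size,
                   weights = sampling_weights(bal),
                   seed = sub_seed(seed, "fusion"),
                   epoch_callback = callback)
  structure(list(net = net, class_names = c("MSS", "MSI"),
                 hidden_units = hidden_units),
            class = "bp_fusion_model")
}

#' Fuse two sub-class models' predictions
#'
#' Applies a fusion model (a trained [train_fusion()] perceptron, or any
#' function mapping the n x 6 concatenated probability matrix to an n x 2
#' MSS/MSI probability matrix) to paired three-class prediction tables.
#' Patches are aligned by `patch_id`; only probabilities are consumed, so
#' inference needs no genomic features.
#'
#' @inheritParams train_fusion
#' @param fusion A `bp_fusion_model` or a function as described above.
#' @return A binary prediction table (`patch_id`, `patient_id`, `MSS`,
#'   `MSI`).
#' @export
combine_predict <- function(preds_a, preds_b, fusion) {
  al <- align_prediction_pair(preds_a, preds_b)
  P <- if (inherits(fusion, "bp_fusion_model")) {
    mlp_predict(fusion$net, al$X)
  } else if (is.function(fusion)) {
    fusion(al$X)
  } else {
    stop_input("fusion must be a bp_fusion_model or a function")
  }
  if (!is.matrix(P) || ncol(P) != 2 || nrow(P) != nrow(al$X)) {
    stop_input("fusion output must be an n x 2 probability matrix")
  }
  data.frame(patch_id = al$patch_id, patient_id = al$patient_id,
             MSS = unname(P[, 1]), MSI = unname(P[, 2]),
             stringsAsFactors = FALSE, row.names = NULL)
}
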