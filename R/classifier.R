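# Patch-level classifiers. The default "small_convnet" backbone is a fixed,
# seeded random-filter convolutional feature bank (conv-ReLU-meanpool x3,
# then global mean and max pooling); only the classification head - one
# hidden ReLU layer and a softmax output of width 2 (baseline) or 3
# (biologically-primed) - is trained, with minibatch Adam, a class-balanced
# weighted sampler, and per-epoch checkpointing on patient-level validation
# AUROC. Baseline and sub-class models therefore differ in nothing but the
# width of the output layer and the label table.

#' Training configuration for patch classifiers
#'
#' @param backbone Feature extractor: only `"small_convnet"` is built in; a
#'   custom backbone can be supplied to [patch_dataset()] as a function.
#' @param n_classes 2 (binary baseline) or 3 (sub-class model).
#' @param learning_rate Adam learning rate. The default (1e-3) suits the
#'   from-scratch classifier head trained here.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param hidden_units Width of the hidden layer shared by both heads.
#' @param weight_decay Decoupled L2 weight-decay coefficient applied to the
#'   head's weight matrices after each Adam step (scaled by the learning
#'   rate); regularizes the small, heavily re-weighted sub-classes.
#' @param backbone_seed Seed for the fixed convolutional filter bank; keep
#'   identical between a baseline and its sub-class counterpart.
#' @param seed RNG seed for head initialization and batch sampling.
#' @return An object of class `bp_training_config`.
#' @export
training_config <- function(backbone = "small_convnet", n_classes = 2,
                            learning_rate = 1e-3, epochs = 15,
                            batch_size = 64, hidden_units = 32,
                            weight_decay = 3, backbone_seed = 42, seed = 1) {
  if (!n_classes %in% 2:3) stop_input("n_classes must be 2 or 3")
  if (learning_rate <= 0) stop_input("learning_rate must be positive")
  if (epochs < 1) stop_input("epochs must be at least 1")
  structure(list(backbone = backbone, n_classes = n_classes,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, hidden_units = hidden_units,
                 weight_decay = weight_decay, backbone_seed = backbone_seed,
                 seed = seed),
            class = "bp_training_config")
}

# Fixed random convolutional filter bank. He-scaled Gaussian filters with
# random biases; deterministic in the backbone seed.
make_backbone <- function(seed = 42, image_size = 64) {
  widths <- list(c(5, 3, 8), c(3, 8, 16), c(3, 16, 32))
  layers <- with_seed(seed, lapply(widths, function(w) {
    k <- w[1]; cin <- w[2]; cout <- w[3]
    list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                    k * k * cin, cout),
         b = stats::rnorm(cout, 0, 0.3), k = k, cin = cin, cout = cout)
  }))
  # precompute im2col index matrices for each stage at this image size
  cache <- list(); h <- image_size
  for (i in seq_along(layers)) {
    cache[[i]] <- im2col_index(h, h, layers[[i]]$cin, layers[[i]]$k)
    h <- (h - layers[[i]]$k + 1) %/% 2
  }
  list(layers = layers, cache = cache, image_size = image_size,
       n_features = 2 * layers[[length(layers)]]$cout, seed = seed)
}

# Column-major linear indices gathering every k x k x cin patch of an
# h x w x cin array into the rows of an (oh*ow) x (k*k*cin) matrix.
im2col_index <- function(h, w, cin, k) {
  oh <- h - k + 1; ow <- w - k + 1
  off <- as.vector(outer(0:(k - 1), (0:(k - 1)) * h, "+"))
  off <- as.vector(outer(off, (0:(cin - 1)) * h * w, "+"))
  start <- as.vector(outer(1:oh, (1:ow - 1) * h, "+"))
  outer(start, off, "+")
}

conv_relu_pool <- function(x, layer, idx) {
  oh <- dim(x)[1] - layer$k + 1; ow <- dim(x)[2] - layer$k + 1
  Z <- matrix(x[idx], nrow(idx)) %*% layer$W
  Z <- sweep(Z, 2, layer$b, "+")
  Z[Z < 0] <- 0
  A <- array(Z, c(oh, ow, layer$cout))
  ph <- oh %/% 2; pw <- ow %/% 2
  (A[seq(1, 2 * ph, 2), seq(1, 2 * pw, 2), , drop = FALSE] +
   A[seq(2, 2 * ph, 2), seq(1, 2 * pw, 2), , drop = FALSE] +
   A[seq(1, 2 * ph, 2), seq(2, 2 * pw, 2), , drop = FALSE] +
   A[seq(2, 2 * ph, 2), seq(2, 2 * pw, 2), , drop = FALSE]) / 4
}

backbone_features <- function(img, backbone) {
  x <- img
  for (i in seq_along(backbone$layers)) {
    x <- conv_relu_pool(x, backbone$layers[[i]], backbone$cache[[i]])
  }
  c(apply(x, 3, mean), apply(x, 3, max))
}

#' Extract backbone features for a cohort's patches
#'
#' Renders (or reads) each patch image and runs it through the fixed
#' convolutional backbone once. The resulting feature table is reused by
#' every model trained on the cohort, which is what makes the paired
#' baseline / sub-class comparisons cheap.
#'
#' @param cohort A `bp_cohort` from [generate_cohort()].
#' @param patch_ids Optional subset of patch ids to featurize.
#' @param backbone_seed Seed of the fixed filter bank.
#' @return An object of class `bp_patch_dataset` with the feature matrix
#'   (`features`, rows named by patch id), `patch_id`, `patient_id`, and
#'   `base_label`.
#' @export
patch_dataset <- function(cohort, patch_ids = NULL, backbone_seed = 42) {
  stopifnot(inherits(cohort, "bp_cohort"))
  rows <- if (is.null(patch_ids)) seq_len(nrow(cohort$patches)) else {
    m <- match(patch_ids, cohort$patches$patch_id)
    if (anyNA(m)) stop_input("unknown patch id(s)")
    m
  }
  bb <- make_backbone(backbone_seed, cohort$config$image_size)
  F <- matrix(0, length(rows), bb$n_features)
  for (j in seq_along(rows)) {
    F[j, ] <- backbone_features(patch_pixels(cohort, rows[j]), bb)
  }
  rownames(F) <- cohort$patches$patch_id[rows]
  structure(list(features = F,
                 patch_id = cohort$patches$patch_id[rows],
                 patient_id = cohort$patches$patient_id[rows],
                 base_label = cohort$patches$base_label[rows],
                 backbone_seed = backbone_seed),
            class = "bp_patch_dataset")
}

dataset_rows <- function(dataset, patient_ids) {
  which(dataset$patient_id %in% patient_ids)
}

# Patient-level binary MSI-vs-MSS AUROC of a head on given dataset rows.
patient_val_auroc <- function(params, X, patient_id, base_label, n_classes) {
  P <- mlp_forward(params, X)
  p_msi <- if (n_classes == 2) P[, 2] else pmax(P[, 2], P[, 3])
  sc <- tapply(p_msi, patient_id, mean)
  lab <- tapply(base_label == "MSI", patient_id, function(z) z[1])
  auroc(as.numeric(sc), as.integer(lab), positive = 1)
}

#' Train a patch classifier
#'
#' Trains the classification head over the fixed backbone features with
#' cross-entropy, Adam, and a class-balanced weighted sampler. After every
#' epoch the patient-level binary MSI-vs-MSS AUROC on the validation
#' patients is computed (sub-class probabilities collapse by the per-patch
#' max rule before averaging) and the best epoch's weights are kept.
#'
#' @param dataset A [patch_dataset()].
#' @param sub_labels Data frame `patient_id`, `sub_label` (use the base
#'   labels as sub-labels for a binary baseline), or `NULL` to train the
#'   binary baseline from the dataset's base labels.
#' @param train_patients,val_patients Character vectors of patient ids.
#' @param config A [training_config()]; its `n_classes` must match the
#'   label set.
#' @return An object of class `bp_model` with the trained head, the ordered
#'   `class_names` (MSS first), feature standardization parameters, and
#'   `best_val_auroc`.
#' @export
train_classifier <- function(dataset, sub_labels = NULL, train_patients,
                             val_patients, config = training_config()) {
  stopifnot(inherits(dataset, "bp_patch_dataset"),
            inherits(config, "bp_training_config"))
  lab_of <- if (is.null(sub_labels)) {
    u <- !duplicated(dataset$patient_id)
    stats::setNames(dataset$base_label[u], dataset$patient_id[u])
  } else {
    check_columns(sub_labels, c("patient_id", "sub_label"), "sub_labels")
    stats::setNames(sub_labels$sub_label, sub_labels$patient_id)
  }
  ti <- dataset_rows(dataset, train_patients)
  vi <- dataset_rows(dataset, val_patients)
  if (!length(ti) || !length(vi)) stop_input("empty training or validation set")
  if (length(unique(dataset$base_label[vi])) < 2) {
    stop_input("validation patients must include both base classes")
  }
  y_lab <- unname(lab_of[dataset$patient_id[ti]])
  if (anyNA(y_lab)) stop_input("sub_labels missing for some training patients")
  class_names <- c("MSS", sort(setdiff(unique(y_lab), "MSS")))
  if (length(class_names) != config$n_classes) {
    stop_input("label set has %d classes but config$n_classes = %d",
               length(class_names), config$n_classes)
  }
  y <- match(y_lab, class_names)
  if (length(unique(y)) < config$n_classes) stop_input("a training class is empty")
  X <- dataset$features[ti, , drop = FALSE]
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xv <- sweep(sweep(dataset$features[vi, , drop = FALSE], 2, mu), 2, sdv, "/")
  val_pid <- dataset$patient_id[vi]
  val_lab <- dataset$base_label[vi]
  net <- mlp_train(X, y, n_classes = config$n_classes,
                   hidden_units = config$hidden_units,
                   epochs = config$epochs,
                   learning_rate = config$learning_rate,
                   batch_size = config$batch_size,
                   weight_decay = config$weight_decay,
                   weights = sampling_weights(y_lab),
                   seed = config$seed,
                   epoch_callback = function(params) {
                     patient_val_auroc(params, Xv, val_pid, val_lab,
                                       config$n_classes)
                   })
  structure(list(net = net, class_names = class_names, config = config,
                 feature_mean = mu, feature_sd = sdv,
                 backbone_seed = dataset$backbone_seed,
                 best_val_auroc = net$best_score),
            class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("Patch classifier: %d classes (%s), best val AUROC %.3f\n",
              length(x$class_names), paste(x$class_names, collapse = ", "),
              x$best_val_auroc))
  invisible(x)
}

#' Predict patch class probabilities
#'
#' Deterministic inference on backbone features: one probability row per
#' patch over the model's class names, each row summing to one. Only the
#' images (through their features) are consumed; no genomic information
#' enters inference.
#'
#' @param model A [train_classifier()] model.
#' @param dataset A [patch_dataset()] built with the same backbone seed.
#' @param patient_ids Optional subset of patients to predict.
#' @return A prediction table: `patch_id`, `patient_id`, and one
#'   probability column per class.
#' @export
predict_classifier <- function(model, dataset, patient_ids = NULL) {
  stopifnot(inherits(model, "bp_model"), inherits(dataset, "bp_patch_dataset"))
  if (!identical(model$backbone_seed, dataset$backbone_seed)) {
    stop_input("dataset backbone seed differs from the model's")
  }
  rows <- if (is.null(patient_ids)) seq_along(dataset$patch_id) else
    dataset_rows(dataset, patient_ids)
  X <- sweep(sweep(dataset$features[rows, , drop = FALSE], 2,
                   model$feature_mean), 2, model$feature_sd, "/")
  P <- mlp_forward(model$net$params, X)
  out <- data.frame(patch_id = dataset$patch_id[rows],
                    patient_id = dataset$patient_id[rows],
                    stringsAsFactors = FALSE)
  for (j in seq_along(model$class_names)) out[[model$class_names[j]]] <- P[, j]
  out
}
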