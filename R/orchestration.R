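# End-to-end experiment driver: simulate -> sub-label -> balance -> folds ->
# train baseline & sub-class models on identical data -> aggregate ->
# evaluate, with optional probability-level fusion of two sub-class models.

#' Experiment configuration
#'
#' Bundles the generator settings, the sub-labeling schemes to evaluate,
#' the fold count, the training settings, and the replicate seeds. Every
#' random stream in the experiment is derived from the replicate seed, so a
#' configuration identifies its results exactly.
#'
#' @param generator A [generator_config()]; its `seed` is overridden per
#'   replicate.
#' @param schemes Named list of [sublabel_scheme()]s to evaluate; each is
#'   compared against a binary baseline retrained on the identical patch
#'   set and fold partition.
#' @param k Number of stratified cross-validation folds.
#' @param training A [training_config()]; `n_classes` is set per model.
#' @param seeds Integer vector of replicate seeds.
#' @param combine Length-2 character vector naming two schemes whose
#'   sub-class models are fused through the probability-level perceptron,
#'   or `NULL` to skip fusion.
#' @return An object of class `bp_experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              schemes = list(snp = sublabel_scheme("snp")),
                              k = 5,
                              training = training_config(),
                              seeds = 1:5,
                              combine = NULL) {
  stopifnot(inherits(generator, "bp_generator_config"),
            inherits(training, "bp_training_config"))
  if (!length(seeds)) stop_input("seeds must be non-empty")
  if (!length(schemes) || is.null(names(schemes)) || any(names(schemes) == "")) {
    stop_input("schemes must be a named list")
  }
  for (s in schemes) stopifnot(inherits(s, "bp_sublabel_scheme"))
  if (!is.null(combine)) {
    if (length(combine) != 2 || !all(combine %in% names(schemes))) {
      stop_input("combine must name two entries of schemes")
    }
  }
  structure(list(generator = generator, schemes = schemes, k = k,
                 training = training, seeds = seeds, combine = combine),
            class = "bp_experiment_config")
}

with_config_seed <- function(cfg, seed) {
  cfg$seed <- seed
  cfg
}

# Train baseline + sub-class model for one scheme on one fold, and return
# per-fold patient-level test scores for both.
train_scheme_fold <- function(dataset, sub, fold_tab, fold, training,
                              test_patients) {
  train_p <- fold_tab$patient_id[fold_tab$fold != fold]
  val_p <- fold_tab$patient_id[fold_tab$fold == fold]
  n_sub <- length(unique(sub$sub_label))
  cfg_bp <- training; cfg_bp$n_classes <- n_sub
  cfg_base <- training; cfg_base$n_classes <- 2
  bp <- train_classifier(dataset, sub, train_p, val_p, cfg_bp)
  base <- train_classifier(dataset, NULL, train_p, val_p, cfg_base)
  list(bp = bp, base = base,
       bp_test = predict_classifier(bp, dataset, test_patients),
       base_test = predict_classifier(base, dataset, test_patients),
       bp_val = predict_classifier(bp, dataset, val_p))
}

#' Run a paired baseline / sub-class experiment on synthetic cohorts
#'
#' For each replicate seed: generates a cohort, balances the training
#' patches at the base-class level, extracts backbone features once, and
#' then, for every scheme, applies the scheme's training exclusion, builds
#' stratified folds on the sub-labels, and trains the sub-class model and
#' its binary baseline on byte-identical patch sets and folds. Both models
#' score the held-out test split of every replicate; patient scores use the
#' max-over-subclass rule followed by patch averaging. When `combine` is
#' set, the two named schemes' fold models are additionally fused through
#' the probability-level perceptron trained on out-of-fold training
#' predictions.
#'
#' @param config An [experiment_config()].
#' @param progress Emit per-seed progress messages.
#' @return An object of class `bp_experiment`: `results` (one row per seed
#'   x scheme x model x fold with patient-level AUROC, AP, and F1),
#'   `scores` (patient-level score tables), and `config`.
#' @export
run_experiment <- function(config, progress = interactive()) {
  stopifnot(inherits(config, "bp_experiment_config"))
  results <- list(); scores <- list()
  for (seed in config$seeds) {
    res <- run_replicate(config, seed, progress)
    results[[length(results) + 1]] <- res$results
    scores[[as.character(seed)]] <- res$scores
  }
  structure(list(results = do.call(rbind, results), scores = scores,
                 config = config),
            class = "bp_experiment")
}

run_replicate <- function(config, seed, progress = FALSE) {
  if (progress) message(sprintf("replicate seed %d: generating cohort", seed))
  cohort <- generate_cohort(with_config_seed(config$generator,
                                             sub_seed(seed, "cohort")))
  patients <- cohort$patients
  train_pat <- patients[patients$split == "train", ]
  test_pat <- patients[patients$split == "test", ]
  train_patches <- cohort$patches[cohort$patches$patient_id %in%
                                    train_pat$patient_id, ]
  balanced <- balance_patches(train_patches, seed = sub_seed(seed, "balance"))
  keep_ids <- c(balanced$patch_id,
                cohort$patches$patch_id[cohort$patches$patient_id %in%
                                          test_pat$patient_id])
  if (progress) message(sprintf("replicate seed %d: extracting features (%d patches)",
                                seed, length(keep_ids)))
  dataset <- patch_dataset(cohort, keep_ids,
                           backbone_seed = config$training$backbone_seed)
  test_labels <- stats::setNames(test_pat$subtype, test_pat$patient_id)

  rows <- list(); sc <- list(); fold_models <- list(); fold_tabs <- list()
  subs <- list()
  for (nm in names(config$schemes)) {
    scheme <- config$schemes[[nm]]
    eligible <- apply_training_exclusion(train_pat, scheme)
    sub <- assign_sublabels(eligible, scheme)
    folds <- stratified_folds(eligible, sub$sub_label[match(eligible$patient_id,
                                                            sub$patient_id)],
                              k = config$k,
                              seed = sub_seed(seed, paste0("folds:", nm)))
    per_fold <- list()
    for (f in sort(unique(folds$fold))) {
      if (progress) message(sprintf("replicate seed %d: scheme %s fold %d",
                                    seed, nm, f))
      tf <- train_scheme_fold(dataset, sub, folds, f, config$training,
                              test_pat$patient_id)
      per_fold[[as.character(f)]] <- tf
      for (model in c("bp", "base")) {
        agg <- aggregate_patients(tf[[paste0(model, "_test")]])
        lab <- test_labels[agg$patient_id]
        rows[[length(rows) + 1]] <- data.frame(
          seed = seed, scheme = nm,
          model = if (model == "bp") "bp" else "baseline", fold = f,
          auroc = auroc(agg$p_msi, lab),
          ap = average_precision(agg$p_msi, lab),
          f1 = best_f1_threshold(agg$p_msi, lab)$f1,
          val_auroc = if (model == "bp") tf$bp$best_val_auroc else
            tf$base$best_val_auroc,
          stringsAsFactors = FALSE)
        sc[[paste(seed, nm, model, f, sep = ":")]] <- agg
      }
    }
    fold_models[[nm]] <- per_fold
    fold_tabs[[nm]] <- folds
    subs[[nm]] <- sub
  }

  if (!is.null(config$combine)) {
    if (progress) message(sprintf("replicate seed %d: fusing %s + %s", seed,
                                  config$combine[1], config$combine[2]))
    comb <- fuse_schemes(dataset, fold_models, fold_tabs, subs, config, seed,
                         test_pat$patient_id)
    for (f in names(comb$per_fold)) {
      agg <- comb$per_fold[[f]]
      lab <- test_labels[agg$patient_id]
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, scheme = paste(config$combine, collapse = "+"),
        model = "combined", fold = as.integer(f),
        auroc = auroc(agg$p_msi, lab),
        ap = average_precision(agg$p_msi, lab),
        f1 = best_f1_threshold(agg$p_msi, lab)$f1,
        val_auroc = NA_real_, stringsAsFactors = FALSE)
      sc[[paste(seed, "combined", f, sep = ":")]] <- agg
    }
  }
  list(results = do.call(rbind, rows), scores = sc)
}

# Fuse two schemes' fold models: the perceptron is trained on out-of-fold
# training-cohort predictions (each patch predicted by the constituent
# whose fold held its patient out), then applied fold-wise to the test set.
fuse_schemes <- function(dataset, fold_models, fold_tabs, subs, config, seed,
                         test_patients) {
  a <- config$combine[1]; b <- config$combine[2]
  oof <- function(nm) {
    folds <- fold_tabs[[nm]]
    parts <- lapply(names(fold_models[[nm]]), function(f) {
      val_p <- folds$patient_id[folds$fold == as.integer(f)]
      predict_classifier(fold_models[[nm]][[f]]$bp, dataset, val_p)
    })
    do.call(rbind, parts)
  }
  pa <- oof(a); pb <- oof(b)
  shared <- intersect(pa$patch_id, pb$patch_id)
  pa <- pa[pa$patch_id %in% shared, ]
  pb <- pb[pb$patch_id %in% shared, ]
  lab <- data.frame(patch_id = dataset$patch_id,
                    base_label = dataset$base_label)
  # balance sampling over scheme A's sub-labels and checkpoint by fold-wise
  # patient AUROC, so the combiner keeps the rare sub-class's signal and is
  # selected under test-like (single fold model) conditions
  sub_a <- subs[[a]]
  folds_a <- fold_tabs[[a]]
  bal <- data.frame(
    patch_id = pa$patch_id,
    label = sub_a$sub_label[match(pa$patient_id, sub_a$patient_id)])
  grp <- data.frame(
    patch_id = pa$patch_id,
    group = folds_a$fold[match(pa$patient_id, folds_a$patient_id)])
  fusion <- train_fusion(pa, pb, lab, balance_labels = bal, val_groups = grp,
                         seed = sub_seed(seed, "fusion"))
  per_fold <- list()
  for (f in names(fold_models[[a]])) {
    fused <- combine_predict(fold_models[[a]][[f]]$bp_test,
                             fold_models[[b]][[f]]$bp_test, fusion)
    per_fold[[f]] <- aggregate_patients(fused)
  }
  list(fusion = fusion, per_fold = per_fold)
}

#' @export
print.bp_experiment <- function(x, ...) {
  cat("Synthetic-cohort experiment\n")
  print(summary_table(x))
  invisible(x)
}

#' Per-seed mean metrics of an experiment
#'
#' Averages the per-fold test metrics within each replicate seed, one row
#' per seed x scheme x model.
#'
#' @param experiment A [run_experiment()] result.
#' @return A data frame with per-seed mean `auroc`, `ap`, and `f1`.
#' @export
seed_means <- function(experiment) {
  r <- experiment$results
  agg <- stats::aggregate(r[c("auroc", "ap", "f1")],
                          by = r[c("seed", "scheme", "model")], mean)
  agg[order(agg$scheme, agg$model, agg$seed), ]
}

summary_table <- function(experiment) {
  m <- seed_means(experiment)
  stats::aggregate(m[c("auroc", "ap", "f1")],
                   by = m[c("scheme", "model")], mean)
}

#' Paired comparison of a sub-class model against its baseline
#'
#' Pairs the per-seed fold-averaged metric of the sub-class (or combined)
#' model with its baseline on the same replicates and applies the paired
#' t-test.
#'
#' @param experiment A [run_experiment()] result.
#' @param scheme Scheme name to compare (or the combined scheme label).
#' @param metric `"auroc"`, `"ap"`, or `"f1"`.
#' @param model Model column value to compare against the baseline,
#'   `"bp"` or `"combined"`.
#' @param baseline_scheme Scheme whose baseline is the reference; defaults
#'   to `scheme` (for the combined model supply one of its constituents).
#' @return A list: per-seed metric vectors for both models and the
#'   [paired_fold_test()] result.
#' @export
compare_to_baseline <- function(experiment, scheme, metric = "auroc",
                                model = "bp", baseline_scheme = scheme) {
  m <- seed_means(experiment)
  a <- m[m$scheme == scheme & m$model == model, ]
  b <- m[m$scheme == baseline_scheme & m$model == "baseline", ]
  if (!nrow(a) || !nrow(b)) stop_input("scheme not found in experiment results")
  a <- a[order(a$seed), ]; b <- b[order(b$seed), ]
  stopifnot(identical(a$seed, b$seed))
  list(seed = a$seed, model = a[[metric]], baseline = b[[metric]],
       test = paired_fold_test(a[[metric]], b[[metric]]))
}

#' Export experiment metrics as JSON
#'
#' Writes the per-fold results table, per-seed means, and summary means to
#' a JSON file.
#'
#' @param experiment A [run_experiment()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_metrics <- function(experiment, path) {
  out <- list(results = experiment$results,
              seed_means = seed_means(experiment),
              summary = summary_table(experiment))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
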