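# Small in-code fixtures shared across test files.

# A hand-written patient table covering both splits and all CIMP levels.
toy_patients <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:8),
    split = c("train", "train", "train", "train", "train", "test", "test", "test"),
    subtype = c("MSI", "MSI", "MSS", "MSS", "MSS", "MSI", "MSS", "MSS"),
    snp_count = c(1500, 1200, 5000, 40, 80, 90, 55, 20),
    cimp_category = c("CIMP-H", "non-CIMP", "CIMP-H", "CIMP-L", "non-CIMP",
                      "CIMP-H", "CIMP-H", "non-CIMP"),
    cnv_fraction = c(0.001, 0.02, 0.3, 0.4, 0.25, 0.003, 0.5, 0.35),
    latent_mode = c("A", "B", "A", "B", "A", "B", "A", "B"),
    n_patches = rep(2L, 8),
    stringsAsFactors = FALSE
  )
}

# A small cohort that renders quickly; used by classifier/orchestration tests.
tiny_generator <- function(seed = 1, n_train = 40, n_test = 20,
                           patches = 4, size = 32) {
  generator_config(n_train_patients = n_train, n_test_patients = n_test,
                   msi_fraction_train = 0.3, msi_fraction_test = 0.3,
                   patches_per_patient = patches, image_size = size,
                   seed = seed)
}

# Random score/label instances; discretized scores force ties.
random_instance <- function(n, seed, p_pos = 0.4, levels = 20) {
  set.seed(seed)
  list(scores = round(stats::runif(n), 2) * levels / levels,
       labels = stats::rbinom(n, 1, p_pos))
}

# O(n^2) pairwise-concordance oracle for the AUROC.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force threshold-enumeration oracle for average precision.
ap_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0; ap <- 0
  for (th in ths) {
    call_pos <- scores >= th
    tp <- sum(labels == 1 & call_pos)
    prec <- tp / sum(call_pos)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Exhaustive-threshold oracle for the best achievable F1.
best_f1_oracle <- function(scores, labels) {
  cand <- sort(unique(c(-1, scores, 2)))
  best <- 0
  for (th in cand) {
    cp <- scores > th
    tp <- sum(labels == 1 & cp); fp <- sum(labels == 0 & cp)
    fn <- sum(labels == 1 & !cp)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best) best <- f1
  }
  best
}
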