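pred_row <- function(patch, patient, ...) {
  data.frame(patch_id = patch, patient_id = patient, ...,
             stringsAsFactors = FALSE)
}

test_that("per-patch MSI probability uses the max-over-subclass rule", {
  p3 <- pred_row("a", "w", MSS = 0.2, MSI1 = 0.3, MSI2 = 0.5)
  expect_equal(patch_msi_probability(p3), 0.5)
  p3b <- pred_row("a", "w", MSS = 0.9, MSI1 = 0.05, MSI2 = 0.05)
  expect_equal(patch_msi_probability(p3b), 0.05)
  p2 <- pred_row("a", "w", MSS = 0.3, MSI = 0.7)
  expect_equal(patch_msi_probability(p2), 0.7)
  bad <- pred_row("a", "w", X = 0.5, Y = 0.5)
  expect_error(patch_msi_probability(bad), "class layout")
})

test_that("patient aggregation is the arithmetic mean of patch MSI probabilities", {
  preds <- data.frame(patch_id = c("a", "b", "c", "d"),
                      patient_id = c("w1", "w1", "w1", "w2"),
                      MSS = 1 - c(0.2, 0.4, 0.9, 0.7),
                      MSI = c(0.2, 0.4, 0.9, 0.7))
  agg <- aggregate_patients(preds)
  expect_equal(agg$p_msi[agg$patient_id == "w1"], 0.5)
  expect_equal(agg$p_msi[agg$patient_id == "w2"], 0.7)
  # brute-force summation oracle on a large random table
  set.seed(21)
  n <- 1000
  p <- runif(n)
  big <- data.frame(patch_id = sprintf("p%04d", 1:n),
                    patient_id = sample(sprintf("w%02d", 1:30), n, TRUE),
                    MSS = 1 - p, MSI = p)
  agg2 <- aggregate_patients(big)
  for (w in unique(big$patient_id)) {
    sel <- big$patient_id == w
    total <- 0
    for (v in big$MSI[sel]) total <- total + v
    expect_equal(agg2$p_msi[agg2$patient_id == w], total / sum(sel),
                 tolerance = 1e-12)
  }
})

test_that("aggregation is permutation-invariant and bounded by its inputs", {
  set.seed(4)
  p <- runif(40)
  preds <- data.frame(patch_id = sprintf("p%02d", 1:40),
                      patient_id = rep(c("w1", "w2"), each = 20),
                      MSS = 1 - p, MSI = p)
  a1 <- aggregate_patients(preds)
  a2 <- aggregate_patients(preds[sample(40), ])
  expect_equal(a1, a2)
  for (w in c("w1", "w2")) {
    v <- p[preds$patient_id == w]
    got <- a1$p_msi[a1$patient_id == w]
    expect_gte(got, min(v)); expect_lte(got, max(v))
  }
})

test_that("three-class collapse then aggregation equals the documented pipeline", {
  set.seed(9)
  n <- 60
  P <- matrix(runif(3 * n), n)
  P <- P / rowSums(P)
  preds <- data.frame(patch_id = sprintf("p%02d", 1:n),
                      patient_id = rep(c("u", "v", "w"), each = 20),
                      MSS = P[, 1], MSI1 = P[, 2], MSI2 = P[, 3])
  agg <- aggregate_patients(preds)
  manual <- tapply(pmax(P[, 2], P[, 3]), preds$patient_id, mean)
  expect_equal(agg$p_msi, as.numeric(manual[agg$patient_id]))
})

test_that("fusion aligns by patch id and a pass-through stub reproduces model A", {
  set.seed(13)
  n <- 80
  mk3 <- function() {
    P <- matrix(runif(3 * n), n); P <- P / rowSums(P)
    data.frame(patch_id = sprintf("p%03d", 1:n),
               patient_id = rep(sprintf("w%02d", 1:8), each = 10),
               MSS = P[, 1], MSI1 = P[, 2], MSI2 = P[, 3])
  }
  a <- mk3(); b <- mk3()
  # stub fusion: collapse A's three classes by the max rule
  stub <- function(X) {
    p <- pmax(X[, 2], X[, 3])
    cbind(1 - p, p)
  }
  fused <- combine_predict(a, b, stub)
  labels <- rep(c(1, 0), length.out = 8)[as.integer(factor(unique(a$patient_id)))]
  agg_f <- aggregate_patients(fused)
  agg_a <- aggregate_patients(a)
  expect_equal(auroc(agg_f$p_msi, labels), auroc(agg_a$p_msi, labels))
  # permuting B's rows changes nothing: alignment is by patch_id
  fused2 <- combine_predict(a, b[sample(n), ], stub)
  expect_equal(fused, fused2)
  # mismatched patch sets are rejected with the symmetric difference named
  expect_error(combine_predict(a[-1, ], b, stub), "p001")
})

test_that("fusion training separates separable inputs and is reproducible", {
  set.seed(5)
  n <- 300
  lab <- rep(c("MSI", "MSS"), each = n / 2)
  shift <- ifelse(lab == "MSI", 1.5, -1.5)
  mk <- function() {
    raw <- cbind(runif(n), runif(n) + shift, runif(n) + shift)
    P <- exp(raw) / rowSums(exp(raw))
    data.frame(patch_id = sprintf("p%03d", 1:n),
               patient_id = rep(sprintf("w%02d", 1:30), each = 10),
               MSS = P[, 1], MSI1 = P[, 2], MSI2 = P[, 3])
  }
  a <- mk(); b <- mk()
  labels <- data.frame(patch_id = a$patch_id, base_label = lab)
  f1 <- train_fusion(a, b, labels, seed = 2)
  f2 <- train_fusion(a, b, labels, seed = 2)
  expect_identical(f1$net$params, f2$net$params)
  fused <- combine_predict(a, b, f1)
  expect_true(all(abs(fused$MSS + fused$MSI - 1) < 1e-6))
  acc <- mean((fused$MSI > 0.5) == (lab == "MSI"))
  expect_gt(acc, 0.95)
})

test_that("null fusion inputs give chance-level patient discrimination", {
  aucs <- sapply(1:3, function(seed) {
    set.seed(seed)
    n <- 400
    mk <- function() {
      P <- matrix(runif(3 * n), n); P <- P / rowSums(P)
      data.frame(patch_id = sprintf("p%03d", 1:n),
                 patient_id = rep(sprintf("w%02d", 1:40), each = 10),
                 MSS = P[, 1], MSI1 = P[, 2], MSI2 = P[, 3])
    }
    a <- mk(); b <- mk()
    lab_pat <- setNames(rep(c("MSI", "MSS"), 20), sprintf("w%02d", 1:40))
    labels <- data.frame(patch_id = a$patch_id,
                         base_label = unname(lab_pat[a$patient_id]))
    fm <- train_fusion(a, b, labels, seed = seed)
    # evaluate on fresh noise tables: held-out inputs, same uninformative labels
    a2 <- mk(); b2 <- mk()
    agg <- aggregate_patients(combine_predict(a2, b2, fm))
    auroc(agg$p_msi, lab_pat[agg$patient_id])
  })
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})
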