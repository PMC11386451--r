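# Patch-level image summaries used to probe phenotype separability without
# a trained model: texture granularity (gradient energy tracks nucleus
# count x perimeter) and a dark-spot cue sensitive to prominent nucleoli.
summary_features <- function(img) {
  lum <- 0.3 * img[, , 1] + 0.6 * img[, , 2] + 0.1 * img[, , 3]
  c(grad = mean(abs(diff(lum))), very_dark = mean(lum < 0.22))
}

test_that("cohort generation is deterministic and splits match configured prevalence", {
  cfg <- generator_config(seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$patches, c2$patches)
  tab <- table(c1$patients$split, c1$patients$subtype)
  expect_equal(unname(tab["train", "MSI"]), 39)   # round(260 * 0.15)
  expect_equal(unname(tab["train", "MSS"]), 221)
  expect_equal(unname(tab["test", "MSI"]), 26)    # round(100 * 0.26)
  # patch records reference their patient's subtype
  m <- match(c1$patches$patient_id, c1$patients$patient_id)
  expect_equal(c1$patches$base_label, c1$patients$subtype[m])
})

test_that("MSI SNP counts are calibrated to the published median and range", {
  cfg <- generator_config(n_train_patients = 4000, msi_fraction_train = 0.5,
                          patches_per_patient = 1, seed = 0)
  pats <- generate_cohort(cfg)$patients
  snp <- pats$snp_count[pats$subtype == "MSI" & pats$split == "train"]
  expect_gte(length(snp), 2000)
  expect_lt(abs(median(snp) - 1432) / 1432, 0.10)
  expect_gte(min(snp), 10)
  expect_lte(max(snp), 17000)
  # MSS SNP counts stay low
  mss <- pats$snp_count[pats$subtype == "MSS"]
  expect_lte(median(mss), 100)
})

test_that("CIMP-H rates match the configured MSI and MSS prevalences", {
  cfg <- generator_config(n_train_patients = 4000, msi_fraction_train = 0.5,
                          patches_per_patient = 2, seed = 0)
  cohort <- generate_cohort(cfg)
  pats <- cohort$patients[cohort$patients$split == "train", ]
  # constant patches per patient: patch-weighted equals patient-weighted
  pp <- merge(cohort$patches, pats, by = "patient_id")
  msi_pp <- pp[pp$base_label == "MSI", ]
  expect_lt(abs(mean(msi_pp$cimp_category == "CIMP-H") - 0.60), 0.05)
  mss_pp <- pp[pp$base_label == "MSS", ]
  expect_lt(abs(mean(mss_pp$cimp_category == "CIMP-H") - 0.05), 0.02)
})

test_that("CNV fractions are low in MSI and elevated, variable in MSS", {
  cfg <- generator_config(n_train_patients = 2000, msi_fraction_train = 0.5,
                          patches_per_patient = 1, seed = 3)
  pats <- generate_cohort(cfg)$patients
  msi <- pats$cnv_fraction[pats$subtype == "MSI"]
  mss <- pats$cnv_fraction[pats$subtype == "MSS"]
  expect_lt(median(msi), 0.005)
  expect_gt(median(mss), 0.1)
  expect_gt(stats::sd(mss), stats::sd(msi))
})

test_that("latent mode is deterministic in the covariate at fidelity 1 and independent at 0", {
  cfg1 <- generator_config(n_train_patients = 2000, msi_fraction_train = 0.5,
                           patches_per_patient = 1, fidelity_snp = 1, seed = 5)
  pats1 <- generate_cohort(cfg1)$patients
  msi1 <- pats1[pats1$subtype == "MSI", ]
  expect_equal(msi1$latent_mode, ifelse(msi1$snp_count > 1432, "A", "B"))

  # independence at fidelity 0: Fisher-combined chi-square p across three
  # replicate cohorts (a single 2000-patient table has a 5% false-alarm rate)
  fisher_combined <- function(ps) {
    1 - stats::pchisq(-2 * sum(log(ps)), df = 2 * length(ps))
  }
  p_snp <- sapply(c(5, 6, 7), function(s) {
    cfg0 <- generator_config(n_train_patients = 4000, msi_fraction_train = 0.5,
                             patches_per_patient = 1, fidelity_snp = 0,
                             fidelity_cimp = 0, seed = s)
    msi0 <- subset(generate_cohort(cfg0)$patients,
                   subtype == "MSI" & split == "train")
    ct <- table(msi0$latent_mode, msi0$snp_count > 1432)
    suppressWarnings(chisq.test(ct)$p.value)
  })
  expect_gt(fisher_combined(p_snp), 0.01)
  # CNV is uncoupled under the defaults
  p_cnv <- sapply(c(5, 6, 7), function(s) {
    cfgd <- generator_config(n_train_patients = 4000, msi_fraction_train = 0.5,
                             patches_per_patient = 1, seed = s)
    msid <- subset(generate_cohort(cfgd)$patients,
                   subtype == "MSI" & split == "train")
    ctd <- table(msid$latent_mode,
                 msid$cnv_fraction > median(msid$cnv_fraction))
    suppressWarnings(chisq.test(ctd)$p.value)
  })
  expect_gt(fisher_combined(p_cnv), 0.01)
})

test_that("patch rendering is deterministic and MSS ignores the mode argument", {
  a <- render_patch("MSI", "A", size = 48, seed = 123)
  b <- render_patch("MSI", "A", size = 48, seed = 123)
  expect_identical(a, b)
  expect_equal(dim(a), c(48, 48, 3))
  expect_true(all(a >= 0 & a <= 1))
  # single MSS phenotype: the mode argument changes nothing
  expect_identical(render_patch("MSS", "A", size = 48, seed = 9),
                   render_patch("MSS", "B", size = 48, seed = 9))
  expect_error(render_patch("MSS", "A", size = 16), "at least 32")
})

test_that("the three phenotypes separate under a depth-0 nearest-centroid rule", {
  # mode A is designed to stand clearly apart from MSS while mode B stays
  # deliberately subtle, so held-out accuracy sits well above the 1/3
  # chance level without approaching a clean-cluster ceiling
  set.seed(77)
  per_class <- 150
  classes <- list(MSS = c("MSS", "A"), A = c("MSI", "A"), B = c("MSI", "B"))
  X <- NULL; y <- NULL
  for (nm in names(classes)) {
    for (i in seq_len(per_class)) {
      img <- render_patch(classes[[nm]][1], classes[[nm]][2], size = 64)
      X <- rbind(X, summary_features(img))
      y <- c(y, nm)
    }
  }
  X <- scale(X)
  train <- rep(c(TRUE, FALSE), length.out = nrow(X))
  cent <- sapply(names(classes), function(nm)
    colMeans(X[train & y == nm, , drop = FALSE]))
  d <- as.matrix(dist(rbind(t(cent), X[!train, ])))[-(1:3), 1:3]
  pred <- names(classes)[apply(d, 1, which.min)]
  acc <- mean(pred == y[!train])
  expect_gt(acc, 0.80)
  # every phenotype beats chance on its own diagonal
  tab <- table(factor(pred, names(classes)), factor(y[!train], names(classes)))
  expect_true(all(diag(tab) / colSums(tab) > 0.5))
})

test_that("manifests round-trip and enforce referential integrity", {
  cohort <- generate_cohort(tiny_generator(seed = 2, n_train = 6, n_test = 4,
                                           patches = 2))
  dir <- tempfile("manifests")
  write_manifests(cohort$patients, cohort$patches, dir)
  back <- read_manifests(dir)
  expect_equal(back$patients, cohort$patients, ignore_attr = TRUE)
  expect_equal(back$patches$patch_id, cohort$patches$patch_id)
  expect_true(all(back$patches$patient_id %in% back$patients$patient_id))
  # orphan patch and empty patch list are rejected
  orphan <- cohort$patches
  orphan$patient_id[1] <- "NOPE"
  expect_error(write_manifests(cohort$patients, orphan, dir), "NOPE")
  expect_error(write_manifests(cohort$patients, cohort$patches[0, ], dir),
               "empty")
})

test_that("written cohorts are byte-identical across runs with one seed", {
  d1 <- tempfile("c1"); d2 <- tempfile("c2")
  g <- tiny_generator(seed = 4, n_train = 4, n_test = 4, patches = 2)
  generate_cohort(g, out_dir = d1)
  generate_cohort(g, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  pngs <- grep("png$", f1, value = TRUE)
  expect_gt(length(pngs), 0)
  h1 <- tools::md5sum(file.path(d1, pngs))
  h2 <- tools::md5sum(file.path(d2, pngs))
  expect_equal(unname(h1), unname(h2))
  # pixels read back from disk equal the lazily rendered ones
  mem <- generate_cohort(g)
  img_disk <- png::readPNG(file.path(d1, "images",
                                     paste0(mem$patches$patch_id[1], ".png")))
  img_mem <- render_patch(mem$patches$base_label[1], mem$patches$latent_mode[1],
                          size = g$image_size, seed = mem$patches$render_seed[1])
  expect_equal(as.vector(img_disk[, , 1:3]),
               as.vector(round(img_mem * 255) / 255), tolerance = 1e-9)
})

test_that("degenerate generator settings are rejected", {
  expect_error(generator_config(msi_fraction_train = 1.2), "proportions")
  expect_error(generator_config(image_size = 16), "at least 32")
  expect_error(generate_cohort(generator_config(n_train_patients = 3,
                                                msi_fraction_train = 0.01)),
               "zero patients")
})
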