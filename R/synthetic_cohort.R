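# Synthetic cohort generator: patients with genomic covariates (SNP count,
# CIMP category, CNV fraction), a latent morphological mode coupled to
# those covariates at a configurable fidelity, and per-patient patch
# images rendered from the (subtype, mode) phenotype.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published TCGA-CRC-DX cohort composition: 15% MSI
#' prevalence in training and 26% in the test split; MSI SNP counts from a
#' heavy-tailed log-normal with median 1432 truncated to \[10, 17000\];
#' uniformly low MSS SNP counts; CIMP-H in 60% of MSI patients versus 5%
#' (train) / 1% (test) of MSS patients; CNV fractions concentrated below
#' 0.005 for MSI and elevated and variable for MSS.
#'
#' Each MSI patient carries a latent morphological mode (A or B) that
#' drives the appearance of their patches. `fidelity_snp`, `fidelity_cimp`,
#' and `fidelity_cnv` set the coupling between mode and each genomic
#' covariate: at fidelity 1 the covariate falls on the mode's side of its
#' population median (or matches the CIMP-H category) deterministically up
#' to the marginal-rate constraint; at fidelity 0 covariate and mode are
#' independent. Defaults couple SNP and CIMP to morphology and leave CNV
#' uncoupled, the regime the package is designed to probe.
#'
#' @param n_train_patients,n_test_patients Patients per split.
#' @param msi_fraction_train,msi_fraction_test MSI prevalence per split; the
#'   MSI count is `round(n * fraction)`, allocated deterministically.
#' @param patches_per_patient Patches per patient: a single count or a
#'   `c(min, max)` range sampled uniformly per patient.
#' @param image_size Patch side length in pixels.
#' @param snp_msi,snp_mss Log-normal SNP-count settings
#'   (`meanlog`, `sdlog`, `min`, `max`).
#' @param cimp_h_fraction_msi,cimp_h_fraction_mss_train,cimp_h_fraction_mss_test
#'   CIMP-H rates; the non-CIMP-H remainder splits equally between CIMP-L
#'   and non-CIMP.
#' @param cnv_msi,cnv_mss Beta parameters `c(shape1, shape2)` for the CNV
#'   fraction.
#' @param fidelity_snp,fidelity_cimp,fidelity_cnv Mode-covariate coupling
#'   strengths in \[0, 1\].
#' @param seed Master RNG seed; the whole cohort (covariates and pixels) is
#'   a deterministic function of the configuration.
#' @return An object of class `bp_generator_config`.
#' @export
generator_config <- function(n_train_patients = 260,
                             n_test_patients = 100,
                             msi_fraction_train = 0.15,
                             msi_fraction_test = 0.26,
                             patches_per_patient = 20,
                             image_size = 64,
                             snp_msi = list(meanlog = log(1432), sdlog = 1.0,
                                            min = 10, max = 17000),
                             snp_mss = list(meanlog = log(60), sdlog = 0.5,
                                            min = 1, max = 800),
                             cimp_h_fraction_msi = 0.60,
                             cimp_h_fraction_mss_train = 0.05,
                             cimp_h_fraction_mss_test = 0.01,
                             cnv_msi = c(1.2, 300),
                             cnv_mss = c(3, 6),
                             fidelity_snp = 1,
                             fidelity_cimp = 1,
                             fidelity_cnv = 0,
                             seed = 1) {
  cfg <- list(n_train_patients = n_train_patients,
              n_test_patients = n_test_patients,
              msi_fraction_train = msi_fraction_train,
              msi_fraction_test = msi_fraction_test,
              patches_per_patient = patches_per_patient,
              image_size = image_size,
              snp_msi = snp_msi, snp_mss = snp_mss,
              cimp_h_fraction_msi = cimp_h_fraction_msi,
              cimp_h_fraction_mss_train = cimp_h_fraction_mss_train,
              cimp_h_fraction_mss_test = cimp_h_fraction_mss_test,
              cnv_msi = cnv_msi, cnv_mss = cnv_mss,
              fidelity_snp = fidelity_snp, fidelity_cimp = fidelity_cimp,
              fidelity_cnv = fidelity_cnv, seed = seed)
  props <- c(msi_fraction_train, msi_fraction_test, cimp_h_fraction_msi,
             cimp_h_fraction_mss_train, cimp_h_fraction_mss_test,
             fidelity_snp, fidelity_cimp, fidelity_cnv)
  if (any(props < 0 | props > 1)) stop_input("proportions must lie in [0, 1]")
  counts <- c(n_train_patients, n_test_patients, patches_per_patient,
              image_size)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop_input("counts must be positive integers")
  }
  if (!length(patches_per_patient) %in% c(1L, 2L)) {
    stop_input("patches_per_patient must be a count or a c(min, max) range")
  }
  if (image_size < 32) stop_input("image_size must be at least 32")
  structure(cfg, class = "bp_generator_config")
}

#' @export
print.bp_generator_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort config: %d train / %d test patients ",
                     "(MSI %.0f%% / %.0f%%), %s patches each, %dpx\n"),
              x$n_train_patients, x$n_test_patients,
              100 * x$msi_fraction_train, 100 * x$msi_fraction_test,
              paste(x$patches_per_patient, collapse = "-"), x$image_size))
  cat(sprintf("  fidelity: snp=%.2f cimp=%.2f cnv=%.2f, seed=%d\n",
              x$fidelity_snp, x$fidelity_cimp, x$fidelity_cnv, x$seed))
  invisible(x)
}

# Truncated log-normal sampler, optionally restricted to one side of the
# distribution's (untruncated) median. Inverse-CDF based, so conditional and
# unconditional draws share one uniform stream.
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi, side = NULL) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  p_med <- 0.5  # median of the untruncated distribution = exp(meanlog)
  bounds <- switch(as.character(side %||% "all"),
                   all = c(p_lo, p_hi),
                   high = c(max(p_lo, p_med), p_hi),
                   low = c(p_lo, min(p_hi, p_med)))
  u <- stats::runif(n, bounds[1], bounds[2])
  stats::qlnorm(u, meanlog, sdlog)
}

# Beta sampler restricted to one side of its median, same mechanism.
rside_beta <- function(n, shape1, shape2, side = NULL) {
  bounds <- switch(as.character(side %||% "all"),
                   all = c(0, 1), high = c(0.5, 1), low = c(0, 0.5))
  u <- stats::runif(n, bounds[1], bounds[2])
  stats::qbeta(u, shape1, shape2)
}

# Sides consistent with a latent mode: mode A pairs with the high-SNP /
# CIMP-H / high-CNV side. A coin with success (1 + fidelity) / 2 decides
# whether the covariate lands on its mode-consistent side.
draw_sides <- function(mode, fidelity) {
  match <- stats::runif(length(mode)) < (1 + fidelity) / 2
  want_high <- mode == "A"
  ifelse(xor(want_high, !match), "high", "low")
}

draw_cimp <- function(mode, is_msi, q, fidelity) {
  n <- length(mode)
  if (is_msi) {
    # maximal mode coupling subject to the marginal CIMP-H rate q with
    # modes drawn 50/50: P(CIMP-H | A) = q + f(1-q), P(CIMP-H | B) = q - f(1-q)
    delta <- fidelity * min(1 - q, q)
    p <- ifelse(mode == "A", q + delta, q - delta)
  } else {
    p <- rep(q, n)
  }
  h <- stats::runif(n) < p
  other <- sample(c("CIMP-L", "non-CIMP"), n, replace = TRUE)
  ifelse(h, "CIMP-H", other)
}

generate_patients_split <- function(config, split) {
  n <- if (split == "train") config$n_train_patients else config$n_test_patients
  frac <- if (split == "train") config$msi_fraction_train else config$msi_fraction_test
  n_msi <- round(n * frac)
  if (n_msi == 0 || n_msi == n) {
    stop_input("split '%s' would contain zero patients of one class", split)
  }
  prefix <- if (split == "train") "TR" else "TE"
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  subtype <- rep(c("MSI", "MSS"), c(n_msi, n - n_msi))
  with_seed(sub_seed(config$seed, paste0("patients:", split)), {
    mode <- sample(c("A", "B"), n, replace = TRUE)
    is_msi <- subtype == "MSI"
    # SNP counts
    snp <- numeric(n)
    snp_side <- draw_sides(mode, config$fidelity_snp)
    for (i in seq_len(n)) {
      d <- if (is_msi[i]) config$snp_msi else config$snp_mss
      snp[i] <- rtrunc_lnorm(1, d$meanlog, d$sdlog, d$min, d$max,
                             side = if (is_msi[i]) snp_side[i] else NULL)
    }
    snp <- round(snp)
    # CIMP category
    q_mss <- if (split == "train") config$cimp_h_fraction_mss_train else
      config$cimp_h_fraction_mss_test
    cimp <- character(n)
    cimp[is_msi] <- draw_cimp(mode[is_msi], TRUE, config$cimp_h_fraction_msi,
                              config$fidelity_cimp)
    cimp[!is_msi] <- draw_cimp(mode[!is_msi], FALSE, q_mss, 0)
    # CNV fraction
    cnv <- numeric(n)
    cnv_side <- draw_sides(mode, config$fidelity_cnv)
    msi_idx <- which(is_msi)
    for (i in seq_len(n)) {
      sh <- if (is_msi[i]) config$cnv_msi else config$cnv_mss
      cnv[i] <- rside_beta(1, sh[1], sh[2],
                           side = if (is_msi[i]) cnv_side[i] else NULL)
    }
    npp <- config$patches_per_patient
    n_patches <- if (length(npp) == 1) rep(npp, n) else
      sample(npp[1]:npp[2], n, replace = TRUE)
    data.frame(patient_id = ids, split = split, subtype = subtype,
               snp_count = snp, cimp_category = cimp, cnv_fraction = cnv,
               latent_mode = mode, n_patches = n_patches,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic patient cohort with patch records
#'
#' Draws the patient tables for both splits and the associated patch
#' records. Patch pixels are a pure function of the per-patch render seed,
#' so images can be materialized lazily; pass `out_dir` to write PNG files
#' and CSV manifests immediately. Two calls with the same configuration
#' produce byte-identical manifests and images.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory. When given, patch PNGs are
#'   written under `out_dir/images/` and `patients.csv` / `patches.csv`
#'   under `out_dir`.
#' @return An object of class `bp_cohort`: a list with `patients`,
#'   `patches` (including the hidden `base_label`, `latent_mode` and
#'   `render_seed` columns used for lazy rendering), and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "bp_generator_config"))
  patients <- rbind(generate_patients_split(config, "train"),
                    generate_patients_split(config, "test"))
  patches <- do.call(rbind, lapply(seq_len(nrow(patients)), function(i) {
    np <- patients$n_patches[i]
    pid <- patients$patient_id[i]
    patch_id <- sprintf("%s_p%03d", pid, seq_len(np))
    data.frame(patch_id = patch_id, patient_id = pid,
               image_path = NA_character_,
               base_label = patients$subtype[i],
               latent_mode = patients$latent_mode[i],
               render_seed = vapply(patch_id, function(id)
                 sub_seed(config$seed, paste0("render:", id)), integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(patches) <- NULL
  cohort <- structure(list(patients = patients, patches = patches,
                           config = config), class = "bp_cohort")
  if (!is.null(out_dir)) cohort <- write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.bp_cohort <- function(x, ...) {
  tab <- table(x$patients$split, x$patients$subtype)
  cat(sprintf("Synthetic cohort: %d patients / %d patches (%dpx)\n",
              nrow(x$patients), nrow(x$patches), x$config$image_size))
  print(tab)
  invisible(x)
}

# Materialize the pixels of one patch row (rendered lazily from its seed,
# or read back from disk when the cohort has been written).
patch_pixels <- function(cohort, i) {
  row <- cohort$patches[i, ]
  if (!is.na(row$image_path)) {
    read_patch_png(row$image_path)
  } else {
    quantize_patch(render_patch(row$base_label, row$latent_mode,
                                size = cohort$config$image_size,
                                seed = row$render_seed))
  }
}

write_cohort <- function(cohort, out_dir) {
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop_input("cannot create output directory %s", out_dir)
  rel <- file.path("images", paste0(cohort$patches$patch_id, ".png"))
  for (i in seq_len(nrow(cohort$patches))) {
    img <- quantize_patch(render_patch(cohort$patches$base_label[i],
                                       cohort$patches$latent_mode[i],
                                       size = cohort$config$image_size,
                                       seed = cohort$patches$render_seed[i]))
    write_patch_png(img, file.path(out_dir, rel[i]))
  }
  cohort$patches$image_path <- file.path(out_dir, rel)
  write_manifests(cohort$patients, cohort$patches, out_dir)
  cohort
}

#' Write patient and patch manifests
#'
#' Writes `patients.csv` and `patches.csv` with a stable column order.
#' Fails if any patch references an unknown patient or the patch list is
#' empty.
#'
#' @param patients Patient table.
#' @param patches Patch table.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files.
#' @export
write_manifests <- function(patients, patches, out_dir) {
  check_columns(patients, c("patient_id", "split", "subtype", "snp_count",
                            "cimp_category", "cnv_fraction", "latent_mode",
                            "n_patches"), "patients")
  check_columns(patches, c("patch_id", "patient_id"), "patches")
  if (!nrow(patches)) stop_input("empty patch list")
  orphan <- setdiff(patches$patient_id, patients$patient_id)
  if (length(orphan)) {
    stop_input("patches reference unknown patient(s): %s",
               paste(utils::head(orphan, 5), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input("cannot create output directory %s", out_dir)
  pat_path <- file.path(out_dir, "patients.csv")
  pch_path <- file.path(out_dir, "patches.csv")
  utils::write.csv(patients[, c("patient_id", "split", "subtype", "snp_count",
                                "cimp_category", "cnv_fraction", "latent_mode",
                                "n_patches")],
                   pat_path, row.names = FALSE)
  if (!"image_path" %in% names(patches)) patches$image_path <- NA_character_
  utils::write.csv(patches[, c("patch_id", "patient_id", "image_path")],
                   pch_path, row.names = FALSE)
  invisible(c(patients = pat_path, patches = pch_path))
}

#' Read patient and patch manifests
#'
#' @param dir Directory containing `patients.csv` and `patches.csv`.
#' @return A list with `patients` and `patches` data frames.
#' @export
read_manifests <- function(dir) {
  pat <- utils::read.csv(file.path(dir, "patients.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  pch <- utils::read.csv(file.path(dir, "patches.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(patch_id = "character",
                                        patient_id = "character"))
  list(patients = pat, patches = pch)
}
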