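# Parametric nuclei-texture renderer. Patches are stylized H&E-like tiles:
# an eosin-toned noisy background with randomly placed hematoxylin-toned
# elliptical "nuclei", optionally carrying a darker nucleolus dot. Each
# (subtype, latent mode) pair has its own parameter set; MSS has a single
# phenotype and ignores the mode argument.

#' Default renderer parameter sets
#'
#' Returns the per-phenotype nucleus parameters used by [render_patch()].
#' Each set gives the Poisson intensity of the nucleus count (`lambda`),
#' the mean and spread of the nucleus radius in pixels (`r_mean`, `r_sd`),
#' the upper bound of the eccentricity draw (`ecc`), and the probability
#' that a nucleus carries a prominent nucleolus (`nucleolus`).
#'
#' The three phenotypes are designed so that MSI mode A (many small,
#' markedly pleomorphic nuclei) is clearly distinct from MSS, while MSI
#' mode B (slightly sparser, slightly larger nuclei with frequent prominent
#' nucleoli) differs from MSS only subtly - a stand-in for the MSI tumours
#' whose morphology is close to typical MSS tissue and which dominate
#' false negatives of a binary classifier.
#'
#' @return A named list with elements `MSS`, `A`, and `B`.
#' @export
render_params <- function() {
  list(
    MSS = list(lambda = 14, r_mean = 3.2, r_sd = 0.5, ecc = 0.40, nucleolus = 0.10),
    A   = list(lambda = 30, r_mean = 2.2, r_sd = 0.8, ecc = 0.80, nucleolus = 0.15),
    B   = list(lambda = 12, r_mean = 3.45, r_sd = 0.65, ecc = 0.44, nucleolus = 0.50)
  )
}

render_background <- function(size) {
  base <- c(0.91, 0.79, 0.87)  # eosin-toned
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + matrix(stats::rnorm(size * size, 0, 0.025), size)
  }
  img
}

#' Render one synthetic tissue patch
#'
#' Draws an 8-bit-equivalent RGB patch (values in \[0, 1\]) for a given
#' subtype and latent morphological mode. MSS patches use a single
#' parameter set regardless of `mode`. With a fixed `seed` the output is
#' bitwise reproducible; with `seed = NULL` the current RNG stream is
#' consumed.
#'
#' @param subtype `"MSI"` or `"MSS"`.
#' @param mode Latent morphological mode, `"A"` or `"B"` (ignored for MSS).
#' @param size Image side length in pixels, at least 32.
#' @param seed Optional integer seed for reproducible rendering.
#' @param params Parameter sets as returned by [render_params()].
#' @return A `size` x `size` x 3 numeric array in \[0, 1\].
#' @examples
#' img <- render_patch("MSI", "A", size = 32, seed = 7)
#' dim(img)
#' @export
render_patch <- function(subtype = c("MSS", "MSI"), mode = c("A", "B"),
                         size = 64, seed = NULL, params = render_params()) {
  subtype <- match.arg(subtype)
  mode <- match.arg(mode)
  if (size < 32) stop_input("patch size must be at least 32 pixels")
  draw <- function() {
    par <- if (subtype == "MSS") params$MSS else params[[mode]]
    img <- render_background(size)
    n <- stats::rpois(1, par$lambda)
    for (k in seq_len(n)) {
      cx <- stats::runif(1, 1, size)
      cy <- stats::runif(1, 1, size)
      r <- max(1.2, stats::rnorm(1, par$r_mean, par$r_sd))
      e <- stats::runif(1, 0, par$ecc)
      th <- stats::runif(1, 0, pi)
      a <- r / sqrt(1 - e^2)   # semi-major
      b <- r * sqrt(1 - e^2)   # semi-minor
      col <- c(0.36, 0.26, 0.55) + stats::rnorm(3, 0, 0.02)  # hematoxylin
      gx <- max(1, floor(cx - a - 1)):min(size, ceiling(cx + a + 1))
      gy <- max(1, floor(cy - a - 1)):min(size, ceiling(cy + a + 1))
      X <- matrix(rep(gx, each = length(gy)), length(gy))
      Y <- matrix(rep(gy, length(gx)), length(gy))
      dx <- X - cx; dy <- Y - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      d <- (u / a)^2 + (v / b)^2
      alpha <- pmin(1, pmax(0, (1.15 - d) / 0.3))  # soft ellipse edge
      has_nucleolus <- stats::runif(1) < par$nucleolus
      if (has_nucleolus) {
        dn <- (u / (0.35 * a))^2 + (v / (0.35 * b))^2
        alpha_n <- pmin(1, pmax(0, (1.2 - dn) / 0.4)) * 0.8
      }
      for (ch in 1:3) {
        sub <- img[gy, gx, ch]
        sub <- sub * (1 - alpha) + col[ch] * alpha
        if (has_nucleolus) sub <- sub * (1 - alpha_n) + (col[ch] * 0.4) * alpha_n
        img[gy, gx, ch] <- sub
      }
    }
    array(pmin(pmax(img, 0), 1), dim(img))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Quantize to 8-bit exactly as the PNG writer will, so in-memory and
# written-to-disk pipelines see identical pixel values.
quantize_patch <- function(img) {
  round(img * 255) / 255
}

write_patch_png <- function(img, path) {
  png::writePNG(img, path)
}

read_patch_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
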