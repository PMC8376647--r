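# Online tile augmentation: spatial (affine + flips), intensity (Gaussian
# noise) and frequency-domain (random radial spectral gain) alterations.

#' Augmentation configuration
#'
#' An identity configuration (all ranges degenerate, flips off, sigma 0,
#' gain range `c(1, 1)`) must return the input bit-exactly, which makes the
#' identity transform always reachable.
#'
#' @param rotation_deg Range `c(lo, hi)` of rotation angles in degrees.
#' @param scale Range of isotropic scale factors.
#' @param shear Range of shear coefficients.
#' @param flip_h,flip_v Allow random horizontal/vertical flips.
#' @param gaussian_noise_sigma Sd of additive Gaussian intensity noise.
#' @param freq_gain Range of the radial spectral gain applied in the
#'   Fourier domain (gain interpolates linearly from one draw at DC to
#'   another at the Nyquist radius).
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_deg = c(0, 0), scale = c(1, 1),
                                shear = c(0, 0), flip_h = FALSE, flip_v = FALSE,
                                gaussian_noise_sigma = 0,
                                freq_gain = c(1, 1)) {
  cfg <- list(rotation_deg = rotation_deg, scale = scale, shear = shear,
              flip_h = flip_h, flip_v = flip_v,
              gaussian_noise_sigma = gaussian_noise_sigma,
              freq_gain = freq_gain)
  if (any(!is.finite(unlist(cfg[c("rotation_deg", "scale", "shear",
                                  "gaussian_noise_sigma", "freq_gain")])))) {
    abort("augmentation ranges must be finite", "ihctriage_config_error")
  }
  structure(cfg, class = "augmentation_config")
}

#' Default training augmentation
#'
#' Light affine jitter, flips, mild Gaussian noise and a gentle spectral
#' gain; regularizes the tile classifiers in place of early stopping.
#' @return An `augmentation_config`.
#' @export
default_augmentation <- function() {
  augmentation_config(rotation_deg = c(0, 360), scale = c(0.9, 1.1),
                      shear = c(-0.05, 0.05), flip_h = TRUE, flip_v = TRUE,
                      gaussian_noise_sigma = 0.02, freq_gain = c(0.8, 1.2))
}

is_identity_aug <- function(cfg) {
  diff(cfg$rotation_deg) == 0 && cfg$rotation_deg[1] %% 360 == 0 &&
    diff(cfg$scale) == 0 && cfg$scale[1] == 1 &&
    diff(cfg$shear) == 0 && cfg$shear[1] == 0 &&
    !cfg$flip_h && !cfg$flip_v &&
    cfg$gaussian_noise_sigma == 0 &&
    diff(cfg$freq_gain) == 0 && cfg$freq_gain[1] == 1
}

# Exact 90-degree-step rotation (pixel permutation, histogram preserved).
rot90k <- function(ch, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(ch)
  if (k == 1) return(t(ch)[, rev(seq_len(nrow(ch))), drop = FALSE])
  if (k == 2) return(ch[rev(seq_len(nrow(ch))), rev(seq_len(ncol(ch))), drop = FALSE])
  t(ch)[rev(seq_len(ncol(ch))), , drop = FALSE]
}

affine_sample <- function(img, angle_deg, scale, shear, flip_h, flip_v) {
  h <- dim(img)[1]; w <- dim(img)[2]
  exact90 <- abs(angle_deg %% 90) < 1e-9 && scale == 1 && shear == 0
  out <- img
  if (exact90) {
    k <- as.integer(round(angle_deg / 90))
    for (c in seq_len(dim(img)[3])) out[, , c] <- rot90k(img[, , c], k)
  } else {
    th <- angle_deg * pi / 180
    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    xo <- matrix(rep(seq_len(w), each = h), h, w) - cx
    yo <- matrix(rep(seq_len(h), w), h, w) - cy
    # inverse map: rotate by -th, unscale, unshear
    xi <- (cos(th) * xo + sin(th) * yo) / scale
    yi <- (-sin(th) * xo + cos(th) * yo) / scale - shear * xi
    xi <- xi + cx; yi <- yi + cy
    # reflect out-of-range coordinates
    refl <- function(v, n) {
      v <- abs(v - 1) %% (2 * (n - 1)) + 1
      ifelse(v > n, 2 * n - v, v)
    }
    xi <- refl(xi, w); yi <- refl(yi, h)
    x0 <- pmin(floor(xi), w - 1); y0 <- pmin(floor(yi), h - 1)
    fx <- xi - x0; fy <- yi - y0
    for (c in seq_len(dim(img)[3])) {
      ch <- img[, , c]
      idx <- function(r, cc) ch[cbind(as.vector(r), as.vector(cc))]
      v <- (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x0 + 1) +
        (1 - fx) * fy * idx(y0 + 1, x0) + fx * fy * idx(y0 + 1, x0 + 1)
      out[, , c] <- matrix(v, h, w)
    }
  }
  if (flip_h) out <- out[, rev(seq_len(w)), , drop = FALSE]
  if (flip_v) out <- out[rev(seq_len(h)), , , drop = FALSE]
  out
}

freq_radial_gain <- function(img, g_dc, g_nyq) {
  h <- dim(img)[1]; w <- dim(img)[2]
  fy <- c(seq(0, floor(h / 2)), seq(-(ceiling(h / 2) - 1), -1)) / h
  fx <- c(seq(0, floor(w / 2)), seq(-(ceiling(w / 2) - 1), -1)) / w
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  rho <- rho / max(rho)
  gain <- g_dc + (g_nyq - g_dc) * rho
  out <- img
  for (c in seq_len(dim(img)[3])) {
    sp <- stats::fft(img[, , c])
    out[, , c] <- Re(stats::fft(sp * gain, inverse = TRUE)) / (h * w)
  }
  pmin(pmax(out, 0), 1)
}

#' Augment a tile
#'
#' Applies a randomly drawn affine transform, flips, Gaussian intensity
#' noise, and a random radial gain on the Fourier magnitude, in that order.
#' Rotations that land on multiples of 90 degrees (with unit scale and no
#' shear) are performed as exact pixel permutations. Uses the current RNG
#' stream; fix the seed for reproducible draws.
#'
#' @param img RGB tile array.
#' @param config An [augmentation_config()].
#' @return Augmented array of the same shape; the input itself (bit-exact)
#'   under an identity configuration.
#' @export
augment_tile <- function(img, config = default_augmentation()) {
  stopifnot_rgb(img)
  if (is_identity_aug(config)) return(img)
  angle <- stats::runif(1, config$rotation_deg[1], config$rotation_deg[2])
  sc <- stats::runif(1, config$scale[1], config$scale[2])
  sh <- stats::runif(1, config$shear[1], config$shear[2])
  fh <- config$flip_h && stats::runif(1) < 0.5
  fv <- config$flip_v && stats::runif(1) < 0.5
  out <- affine_sample(img, angle, sc, sh, fh, fv)
  if (diff(config$freq_gain) != 0 || config$freq_gain[1] != 1) {
    g <- stats::runif(2, config$freq_gain[1], config$freq_gain[2])
    out <- freq_radial_gain(out, g[1], g[2])
  }
  if (config$gaussian_noise_sigma > 0) {
    out <- out + array(stats::rnorm(length(out), 0, config$gaussian_noise_sigma),
                       dim = dim(out))
    out <- pmin(pmax(out, 0), 1)
  }
  out
}
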