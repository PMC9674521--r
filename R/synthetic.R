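#' Generate a clean test phantom
#'
#' Deterministic synthetic scenes with known ground truth:
#'
#' * `"blobs"` -- randomly placed 2D Gaussian bumps on a dark background,
#'   emulating the look of fluorescence microscopy (bright puncta, smooth
#'   intensity falloff, mostly-dark field).
#' * `"ramp"` -- a linear gradient along columns.
#' * `"sinusoid"` -- a separable low-frequency sine pattern.
#' * `"chequer_texture"` -- a pixel-level alternating pattern. This is the
#'   deliberate adversarial case: horizontally adjacent clean pixels differ
#'   by the full intensity range, so the neighbour-similarity assumption
#'   behind the chequerboard pairing fails by construction.
#'
#' The three smooth kinds have small adjacent-pixel differences relative to
#' the range, which is the regime in which mapping a downsample onto its
#' parity complement is an (almost) unbiased Noise2Noise objective.
#'
#' @param kind phantom type, see above.
#' @param size `c(m, n)` with both at least 16.
#' @param range intensity range `c(low, high)` of the clean signal.
#' @param n_blobs number of Gaussian bumps (`"blobs"` only; 0 gives a
#'   constant background).
#' @param frequency cycles per axis (`"sinusoid"` only).
#' @param seed integer seed; the same seed always reproduces the phantom.
#' @return list of class `n2f_phantom`: `clean` matrix, `kind`, `range`,
#'   `seed`.
#' @export
make_phantom <- function(kind = c("blobs", "ramp", "sinusoid",
                                  "chequer_texture"),
                         size = c(96L, 96L), range = c(0, 255),
                         n_blobs = 12L, frequency = 1, seed = 1L) {
  kind <- match.arg(kind)
  m <- as.integer(size[1]); n <- as.integer(size[2])
  if (m < 16L || n < 16L) stop_n2f("phantom must be at least 16 x 16")
  lo <- range[1]; hi <- range[2]
  i0 <- matrix(0:(m - 1L), m, n)
  j0 <- matrix(0:(n - 1L), m, n, byrow = TRUE)
  clean <- switch(kind,
    ramp = lo + (hi - lo) * j0 / (n - 1L),
    sinusoid = lo + (hi - lo) *
      (0.5 + 0.5 * sin(2 * pi * frequency * i0 / m) *
                   sin(2 * pi * frequency * j0 / n)),
    chequer_texture = lo + (hi - lo) * ((i0 + j0) %% 2),
    blobs = with_seed(seed, {
      bg <- lo + 0.08 * (hi - lo)
      img <- matrix(bg, m, n)
      if (n_blobs > 0L) {
        ci <- runif(n_blobs, 0, m - 1)
        cj <- runif(n_blobs, 0, n - 1)
        sd <- runif(n_blobs, 4, 10)
        amp <- runif(n_blobs, 0.24, 0.63) * (hi - lo)
        for (b in seq_len(n_blobs)) {
          img <- img + amp[b] *
            exp(-((i0 - ci[b])^2 + (j0 - cj[b])^2) / (2 * sd[b]^2))
        }
      }
      pmin(img, hi)
    }))
  structure(list(clean = clean, kind = kind, range = c(lo, hi),
                 seed = as.integer(seed)),
            class = "n2f_phantom")
}

realization <- function(clean, noisy, kind, sigma, gain, seed) {
  structure(list(noisy = noisy, clean = clean, noise = noisy - clean,
                 noise_kind = kind, sigma = sigma, gain = gain,
                 seed = as.integer(seed)),
            class = "n2f_realization")
}

#' Add i.i.d. Gaussian noise to a clean image
#'
#' Noise is parameterized on the image's native intensity scale (sigma = 25
#' on a 0--255 image matches the usual benchmark convention) and the result
#' is NOT clipped: values may leave the nominal range, exactly as raw
#' detector data would after background subtraction.
#'
#' @param img clean image: matrix, [image2d()] or [make_phantom()] output.
#' @param sigma Gaussian standard deviation, intensity units.
#' @param seed integer seed.
#' @return list of class `n2f_realization` with `noisy`, `clean`, the exact
#'   `noise` field, and the generator parameters.
#' @export
add_gaussian_noise <- function(img, sigma, seed = 1L) {
  if (inherits(img, "n2f_phantom")) img <- img$clean
  clean <- as_pixel_matrix(img)
  if (sigma <= 0) stop_n2f("sigma must be positive")
  noise <- with_seed(seed,
    matrix(rnorm(length(clean), 0, sigma), nrow(clean), ncol(clean)))
  realization(clean, clean + noise, "gaussian", sigma, NA_real_, seed)
}

#' Add Poisson (shot) noise, optionally mixed with Gaussian read noise
#'
#' Each pixel is drawn as `Poisson(clean * gain) / gain`, so the variance at
#' a pixel with clean value `c` is `c / gain` -- the signal-dependent shot
#' noise of photon counting, with `gain` playing the role of detected
#' photons per intensity unit. With `sigma > 0`, Gaussian noise is added on
#' top (the mixed Poisson--Gaussian model typical of confocal microscopy).
#'
#' @param img clean image with nonnegative values.
#' @param gain photons per intensity unit; larger is cleaner.
#' @param seed integer seed.
#' @param sigma optional Gaussian component, intensity units (0 = none).
#' @return list of class `n2f_realization`.
#' @export
add_poisson_noise <- function(img, gain, seed = 1L, sigma = 0) {
  if (inherits(img, "n2f_phantom")) img <- img$clean
  clean <- as_pixel_matrix(img)
  if (any(clean < 0)) stop_n2f("Poisson noise requires nonnegative intensities")
  if (gain <= 0) stop_n2f("gain must be positive")
  noisy <- with_seed(seed, {
    shot <- matrix(rpois(length(clean), clean * gain) / gain,
                   nrow(clean), ncol(clean))
    if (sigma > 0) {
      shot + matrix(rnorm(length(clean), 0, sigma), nrow(clean), ncol(clean))
    } else shot
  })
  realization(clean, noisy, if (sigma > 0) "mixed" else "poisson",
              if (sigma > 0) sigma else NA_real_, gain, seed)
}

#' Run the denoiser on a synthetic phantom and score it
#'
#' Convenience wrapper used by the worked examples and the reproduction
#' script: generate a phantom, add Gaussian noise, run [noise2fast()] with
#' ground-truth tracking, and report PSNR/SSIM of the noisy and denoised
#' images against the clean truth.
#'
#' @param kind phantom kind, see [make_phantom()].
#' @param size image size `c(m, n)`.
#' @param sigma Gaussian noise SD on the phantom's intensity scale.
#' @param seed seed used for the phantom, the noise and the training run.
#' @param net,control architecture and training schedule; the defaults here
#'   are the package's desk-scale testing configuration (a reduced network
#'   and iteration cap that keep a single-CPU run in the tens of seconds).
#' @return list with the `fit`, the `phantom`, the noisy `realization`, and
#'   scalars `psnr_noisy`, `psnr_denoised`, `gain_db`, `ssim_noisy`,
#'   `ssim_denoised`.
#' @export
denoise_phantom <- function(kind = "blobs", size = c(96L, 96L), sigma = 25,
                            seed = 1L,
                            net = network_config(block_widths = c(16L, 32L)),
                            control = trainer_config(max_iterations = 2000L,
                                                     seed = seed)) {
  ph <- make_phantom(kind, size = size, seed = seed)
  rz <- add_gaussian_noise(ph, sigma = sigma, seed = seed)
  fit <- noise2fast(rz$noisy, net = net, control = control,
                    reference = ph$clean)
  dr <- diff(range(ph$clean))
  list(fit = fit, phantom = ph, realization = rz,
       psnr_noisy = psnr(rz$noisy, ph$clean, dr),
       psnr_denoised = psnr(fitted(fit), ph$clean, dr),
       gain_db = psnr(fitted(fit), ph$clean, dr) - psnr(rz$noisy, ph$clean, dr),
       ssim_noisy = ssim(rz$noisy, ph$clean, dr),
       ssim_denoised = ssim(fitted(fit), ph$clean, dr))
}
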