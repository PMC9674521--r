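#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(\mathrm{range}^2 / \mathrm{MSE})} in decibels, capped
#' at 100 dB so identical images yield a finite value in traces.
#'
#' @param a,b numeric matrices of the same shape; `b` is the reference.
#' @param data_range intensity range of the data; defaults to the
#'   reference's `max - min` (the validation loop fixes it at 1).
#' @param cap value returned when MSE is 0 (and an upper bound overall).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range = NULL, cap = 100) {
  a <- as_pixel_matrix(a); b <- as_pixel_matrix(b)
  if (!all(dim(a) == dim(b))) stop_n2f("images must share a shape")
  if (is.null(data_range)) data_range <- diff(range(b))
  if (!is.numeric(data_range) || data_range <= 0)
    stop_n2f("data_range must be positive")
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  min(10 * log10(data_range^2 / mse), cap)
}

ssim_kernel <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2L
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

# Banded matrix applying the 1D kernel over fully supported positions, so
# filt_row %*% x %*% t(filt_row(ncol)) is the valid-region separable filter.
valid_filter_matrix <- function(n, g) {
  k <- length(g)
  t <- matrix(0, n - k + 1L, n)
  for (i in seq_len(n - k + 1L)) t[i, i:(i + k - 1L)] <- g
  t
}

#' Structural similarity index
#'
#' Mean local SSIM over an 11 x 11 Gaussian window (sigma 1.5) with the
#' conventional stabilizers K1 = 0.01, K2 = 0.03, computed on fully
#' supported (interior) windows only. Symmetric in its arguments; equals 1
#' exactly when the images are identical.
#'
#' @param a,b numeric matrices of the same shape, both sides at least 11.
#' @param data_range intensity range; defaults to the reference `b`'s
#'   `max - min`.
#' @return SSIM in \eqn{[-1, 1]}.
#' @export
ssim <- function(a, b, data_range = NULL) {
  a <- as_pixel_matrix(a); b <- as_pixel_matrix(b)
  if (!all(dim(a) == dim(b))) stop_n2f("images must share a shape")
  if (min(dim(a)) < 11L)
    stop_n2f("images must be at least 11 x 11 for the SSIM window")
  if (is.null(data_range)) data_range <- diff(range(b))
  if (!is.numeric(data_range) || data_range <= 0)
    stop_n2f("data_range must be positive")
  g <- ssim_kernel()
  tr <- valid_filter_matrix(nrow(a), g)
  tc <- t(valid_filter_matrix(ncol(a), g))
  f <- function(x) tr %*% x %*% tc
  ux <- f(a); uy <- f(b)
  vx <- f(a * a) - ux^2
  vy <- f(b * b) - uy^2
  cxy <- f(a * b) - ux * uy
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * ux * uy + c1) * (2 * cxy + c2)) /
       ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' PSNR and SSIM of an image against a reference
#'
#' @param a image under test.
#' @param b reference image.
#' @param data_range intensity range; defaults to the reference's range.
#' @return list with `psnr_db`, `ssim` and the `data_range` used.
#' @export
metric_report <- function(a, b, data_range = NULL) {
  if (is.null(data_range)) data_range <- diff(range(as_pixel_matrix(b)))
  list(psnr_db = psnr(a, b, data_range), ssim = ssim(a, b, data_range),
       data_range = data_range)
}
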