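# Shared fixtures and independent oracles for the test suite.

random_image <- function(m, n, seed, max = 255L) {
  noise2fast:::with_seed(seed,
    matrix(as.double(sample.int(max, m * n, replace = TRUE)), m, n))
}

# Independent brute-force oracle for the chequerboard split: walk the pixel
# lattice, collect each parity class ((i+j) even vs odd, 0-based), and close
# ranks along the compression axis. Deliberately written as plain loops,
# sharing no code with the package implementation.
oracle_up <- function(x) {
  m <- nrow(x); n <- ncol(x)
  if (n %% 2 == 1) x <- x[, -n, drop = FALSE]
  n <- ncol(x)
  even <- matrix(NA_real_, m, n / 2)
  odd <- matrix(NA_real_, m, n / 2)
  for (i in seq_len(m)) {
    ke <- 1L; ko <- 1L
    for (j in seq_len(n)) {
      if ((i - 1 + j - 1) %% 2 == 0) {
        even[i, ke] <- x[i, j]; ke <- ke + 1L
      } else {
        odd[i, ko] <- x[i, j]; ko <- ko + 1L
      }
    }
  }
  list(even = even, odd = odd)
}

oracle_left <- function(x) {
  m <- nrow(x); n <- ncol(x)
  if (m %% 2 == 1) x <- x[-m, , drop = FALSE]
  m <- nrow(x)
  even <- matrix(NA_real_, m / 2, n)
  odd <- matrix(NA_real_, m / 2, n)
  for (j in seq_len(n)) {
    ke <- 1L; ko <- 1L
    for (i in seq_len(m)) {
      if ((i - 1 + j - 1) %% 2 == 0) {
        even[ke, j] <- x[i, j]; ke <- ke + 1L
      } else {
        odd[ko, j] <- x[i, j]; ko <- ko + 1L
      }
    }
  }
  list(even = even, odd = odd)
}

tiny_net <- function() network_config(block_widths = c(8L, 16L))

quick_control <- function(seed = 1L, max_iterations = 300L,
                          validation_interval = 50L, patience = 3L) {
  trainer_config(max_iterations = max_iterations,
                 validation_interval = validation_interval,
                 patience = patience, seed = seed)
}

# The desk-scale study configuration shared by the pipeline-level checks:
# 96 x 96 blobs phantom, Gaussian sigma = 25 on the 0-255 scale, reduced
# network (widths 16, 32), at most 2000 iterations. Runs are cached so the
# same fit can back several properties without retraining.
study_run <- local({
  cache <- new.env(parent = emptyenv())
  function(seed, exact_correction = FALSE) {
    key <- paste0("s", seed, if (exact_correction) "_exact" else "")
    if (is.null(cache[[key]])) {
      ph <- make_phantom("blobs", size = c(96L, 96L), seed = seed)
      rz <- add_gaussian_noise(ph, sigma = 25, seed = seed)
      fit <- noise2fast(rz$noisy,
                        net = network_config(block_widths = c(16L, 32L)),
                        control = trainer_config(max_iterations = 2000L,
                                                 seed = seed),
                        reference = ph$clean,
                        exact_correction = exact_correction)
      dr <- diff(range(ph$clean))
      cache[[key]] <- list(
        phantom = ph, realization = rz, fit = fit,
        psnr_noisy = psnr(rz$noisy, ph$clean, dr),
        psnr_denoised = psnr(fitted(fit), ph$clean, dr))
    }
    cache[[key]]
  }
})
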