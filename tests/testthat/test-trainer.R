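test_that("BCE loss matches closed-form values and the clamping contract", {
  half <- matrix(0.5, 4, 4)
  expect_equal(bce_loss(half, half), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(matrix(0.9, 3, 3), matrix(1, 3, 3)), -log(0.9),
               tolerance = 1e-12)
  # perfect prediction under clamping: loss -> ~1e-7
  expect_lt(bce_loss(matrix(1e-7, 2, 2), matrix(0, 2, 2)), 1e-6)
  expect_gt(bce_loss(matrix(1e-7, 2, 2), matrix(0, 2, 2)), 0)
  # clamping keeps the loss finite even for saturated predictions
  expect_true(is.finite(bce_loss(matrix(1, 2, 2), matrix(0, 2, 2))))
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 3)), "shape")
})

test_that("a training step updates the weights and reports the pre-update loss", {
  net <- build_network(tiny_net(), seed = 1)
  x <- normalize_image(random_image(24, 24, seed = 2))
  pair <- build_training_set(x)[[1]]
  st <- train_step(net, pair, quick_control())
  expect_false(identical(st$net$weights, net$weights))
  expect_equal(st$loss, bce_loss(forward_pass(net, pair$input), pair$target),
               tolerance = 1e-12)
  # Adam state advances
  expect_equal(st$state$t, 1)
  st2 <- train_step(st$net, pair, quick_control(), st$state)
  expect_equal(st2$state$t, 2)
})

test_that("training on an identity task descends", {
  net <- build_network(tiny_net(), seed = 3)
  img <- make_phantom("sinusoid", size = c(32L, 32L))$clean / 255
  pair <- list(input = img, target = img, tag = "identity")
  state <- NULL
  first <- NA
  cur <- net
  for (i in 1:500) {
    st <- train_step(cur, pair, quick_control(), state)
    cur <- st$net; state <- st$state
    if (i == 1) first <- st$loss
  }
  final <- bce_loss(forward_pass(cur, img), img)
  expect_lt(final, first)
})

test_that("identical seeds give bit-identical loss sequences and results", {
  noisy <- add_gaussian_noise(make_phantom("blobs", size = c(48L, 48L), seed = 5),
                              sigma = 25, seed = 5)$noisy
  ctl <- quick_control(seed = 9, max_iterations = 200L)
  f1 <- noise2fast(noisy, net = tiny_net(), control = ctl)
  f2 <- noise2fast(noisy, net = tiny_net(), control = ctl)
  expect_identical(f1$trace$losses, f2$trace$losses)
  expect_identical(f1$denoised, f2$denoised)
  f3 <- noise2fast(noisy, net = tiny_net(), control = quick_control(seed = 10,
                                                  max_iterations = 200L))
  expect_false(identical(f1$trace$losses, f3$trace$losses))
})

test_that("validation PSNR is computed in normalized space only", {
  net <- build_network(tiny_net(), seed = 1)
  x <- random_image(24, 24, seed = 3)
  a <- normalize_image(x)
  b <- normalize_image(x * 40 - 1000)  # same normalized pixels, other scale
  expect_equal(a$pixels, b$pixels, tolerance = 1e-12)
  expect_equal(validate_psnr(net, a), validate_psnr(net, b), tolerance = 1e-9)
  expect_gt(validate_psnr(net, a), 0)
  expect_error(validate_psnr(net, normalize_image(matrix(2, 4, 4))),
               "degenerate")
})

test_that("early stopping keeps the best checkpoint, not the final iterate", {
  run <- study_run(1)
  fit <- run$fit
  v <- fit$trace$validations
  expect_identical(fit$trace$best_iteration,
                   v$iteration[which.max(v$psnr)])
  if (fit$trace$stopped_reason == "patience") {
    patience <- fit$settings$control$patience
    tail_psnr <- v$psnr[(nrow(v) - patience + 1):nrow(v)]
    expect_true(all(tail_psnr <= max(v$psnr)))
    expect_lt(fit$trace$best_iteration, max(v$iteration))
  }
  # the returned image is the best-checkpoint forward pass, denormalized
  xn <- normalize_image(run$realization$noisy)
  expect_identical(fit$denoised,
                   denormalize_image(xn, forward_pass(fit$network, xn$pixels)))
  expect_equal(validate_psnr(fit$network, xn), max(v$psnr), tolerance = 1e-9)
})

test_that("a constant image is returned unchanged without training", {
  k <- matrix(42, 32, 32)
  fit <- noise2fast(k, net = tiny_net(), control = quick_control())
  expect_identical(fitted(fit), k)
  expect_identical(fit$trace$stopped_reason, "degenerate_input")
  expect_length(fit$trace$losses, 0L)
})

test_that("split inference reassembles per-downsample outputs at full size", {
  noisy <- add_gaussian_noise(make_phantom("blobs", size = c(32L, 32L), seed = 7),
                              sigma = 25, seed = 7)$noisy
  ctl <- quick_control(seed = 7, max_iterations = 200L)
  fs <- noise2fast(noisy, net = tiny_net(), control = ctl, inference = "split")
  expect_identical(dim(fitted(fs)), dim(noisy))
  fs2 <- noise2fast(noisy, net = tiny_net(), control = ctl, inference = "split")
  expect_identical(fitted(fs), fitted(fs2))
  # split output is the reassembly of the two per-downsample passes
  xn <- normalize_image(noisy)
  up <- downsample_up(xn$pixels)
  expect_identical(fitted(fs),
                   denormalize_image(xn,
                     reassemble_up(forward_pass(fs$network, up$even),
                                   forward_pass(fs$network, up$odd))))
})

test_that("exact-correction targets reduce to the originals for constant truth", {
  x <- normalize_image(random_image(16, 16, seed = 1))
  pairs <- build_training_set(x)
  corrected <- exact_correction_targets(pairs, matrix(0.5, 16, 16))
  for (k in seq_along(pairs)) {
    expect_equal(corrected[[k]]$target, pairs[[k]]$target, tolerance = 1e-12)
  }
  expect_error(exact_correction_targets(pairs, matrix(0.5, 8, 8)),
               "shape")
})

test_that("correction terms are small for smooth truth (the pairing is almost Noise2Noise)", {
  ph <- make_phantom("blobs", size = c(64L, 64L), seed = 2)
  rz <- add_gaussian_noise(ph, sigma = 25, seed = 2)
  xn <- normalize_image(rz$noisy)
  pairs <- build_training_set(xn)
  clean_norm <- (ph$clean - xn$offset) / xn$scale
  corrected <- exact_correction_targets(pairs, pmin(pmax(clean_norm, 0), 1))
  sigma_norm <- 25 / xn$scale
  for (k in seq_along(pairs)) {
    shift <- mean(abs(corrected[[k]]$target - pairs[[k]]$target))
    expect_lt(shift, 0.5 * sigma_norm)
  }
})

test_that("training directly on two noisy realizations also denoises (Noise2Noise sanity)", {
  ph <- make_phantom("blobs", size = c(48L, 48L), seed = 4)
  r1 <- add_gaussian_noise(ph, sigma = 25, seed = 41)
  r2 <- add_gaussian_noise(ph, sigma = 25, seed = 42)
  lo <- min(r1$noisy, r2$noisy); hi <- max(r1$noisy, r2$noisy)
  x1 <- (r1$noisy - lo) / (hi - lo)
  x2 <- (r2$noisy - lo) / (hi - lo)
  net <- build_network(tiny_net(), seed = 4)
  state <- NULL
  pairs <- list(list(input = x1, target = x2), list(input = x2, target = x1))
  for (i in 1:400) {
    st <- train_step(net, pairs[[1 + i %% 2]], quick_control(), state)
    net <- st$net; state <- st$state
  }
  clean_norm <- (ph$clean - lo) / (hi - lo)
  expect_gt(psnr(forward_pass(net, x1), clean_norm, 1),
            psnr(x1, clean_norm, 1))
})
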