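#' Training configuration
#'
#' Defaults follow the method's published training recipe where one exists
#' (Adam, learning rate 0.001, batch size 1) and declared choices where the
#' schedule is unpublished: validate every 100 iterations, stop after 10
#' validations without improvement, cap at 30,000 iterations, and return
#' the best validation checkpoint.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size fixed at 1: pairs are fed one by one.
#' @param max_iterations hard cap on training iterations.
#' @param validation_interval iterations between validations against the
#'   noisy input.
#' @param patience validations without improvement before stopping.
#' @param seed integer seed for weight initialization and pair sampling.
#' @param pair_sampling `"uniform_random"` (seeded) or `"cyclic"`.
#' @param beta1,beta2,epsilon Adam moment parameters (conventional defaults).
#' @return an object of class `n2f_control`.
#' @export
trainer_config <- function(learning_rate = 0.001, batch_size = 1L,
                           max_iterations = 30000L,
                           validation_interval = 100L, patience = 10L,
                           seed = 1L,
                           pair_sampling = c("uniform_random", "cyclic"),
                           beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  if (learning_rate <= 0) stop_n2f("learning_rate must be positive")
  if (batch_size != 1L) stop_n2f("batch_size is fixed at 1")
  if (max_iterations < validation_interval)
    stop_n2f("max_iterations must be at least validation_interval")
  if (patience < 1L) stop_n2f("patience must be at least 1")
  structure(list(learning_rate = learning_rate, batch_size = 1L,
                 max_iterations = as.integer(max_iterations),
                 validation_interval = as.integer(validation_interval),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 pair_sampling = match.arg(pair_sampling),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "n2f_control")
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of \eqn{-[t \log p + (1-t) \log(1-p)]} with predictions
#' clamped to `[1e-7, 1 - 1e-7]`. This is the training loss; the sigmoid
#' head keeps predictions inside (0, 1) and normalization keeps targets
#' inside \eqn{[0,1]}.
#'
#' @param pred matrix of predictions in (0, 1).
#' @param target matrix of targets in \eqn{[0,1]}, same shape.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(pred, target) {
  if (!all(dim(pred) == dim(target)))
    stop_n2f("pred and target must share a shape")
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Fresh Adam optimizer state for a network
#' @param net an `n2f_network`.
#' @return an object of class `n2f_adam` (zeroed first/second moments).
#' @export
adam_state <- function(net) {
  stopifnot(inherits(net, "n2f_network"))
  zW <- lapply(net$weights, function(l) array(0, dim(l$W)))
  zb <- lapply(net$weights, function(l) numeric(length(l$b)))
  structure(list(mW = zW, vW = zW, mb = zb, vb = zb, t = 0), class = "n2f_adam")
}

flatten_pairs <- function(pairs) {
  list(inputs = lapply(pairs, function(p) {
         matrix(as.vector(p$input), length(p$input), 1L)
       }),
       targets = lapply(pairs, function(p) {
         matrix(as.vector(p$target), length(p$target), 1L)
       }),
       H = vapply(pairs, function(p) nrow(p$input), 0L),
       W = vapply(pairs, function(p) ncol(p$input), 0L))
}

run_chunk <- function(net, flat, order, control, state) {
  res <- .cpp_train_chunk(net_W(net), net_b(net), net_k(net),
                          unclass(state), flat$inputs, flat$targets,
                          flat$H, flat$W, as.integer(order),
                          control$learning_rate, control$beta1,
                          control$beta2, control$epsilon)
  for (l in seq_along(net$weights)) {
    net$weights[[l]]$W <- res$W[[l]]
    net$weights[[l]]$b <- as.numeric(res$b[[l]])
  }
  state <- structure(res$adam, class = "n2f_adam")
  list(net = net, state = state, losses = as.numeric(res$losses))
}

#' One optimization step on a single training pair
#'
#' Performs one Adam update of all weights on the gradient of
#' [bce_loss()] between the network output on `pair$input` and
#' `pair$target` (batch size 1), returning the pre-update loss.
#'
#' @param net an `n2f_network`.
#' @param pair a training pair `list(input, target)` in normalized space.
#' @param control an [trainer_config()] object.
#' @param state an [adam_state()] (a fresh one is created if `NULL`).
#' @return list with the updated `net`, scalar `loss`, and `state`.
#' @export
train_step <- function(net, pair, control = trainer_config(), state = NULL) {
  if (!all(dim(pair$input) == dim(pair$target)))
    stop_n2f("pair input and target must share a shape")
  if (is.null(state)) state <- adam_state(net)
  flat <- flatten_pairs(list(pair))
  res <- run_chunk(net, flat, 1L, control, state)
  list(net = res$net, loss = res$losses[1], state = res$state)
}

#' Validation score against the noisy input
#'
#' The stopping signal: PSNR (data range 1, normalized space) between the
#' network applied to the original noisy image and that image itself. The
#' chequerboard downsamples look nothing like the full image at a local
#' level, so the noisy image acts as held-out data, and this self-map
#' score peaks at roughly the same time as the (unobservable) ground-truth
#' score.
#'
#' @param net an `n2f_network`.
#' @param x_norm an `n2f_normalized` image (not degenerate).
#' @return validation PSNR in dB.
#' @export
validate_psnr <- function(net, x_norm) {
  stopifnot(inherits(x_norm, "n2f_normalized"))
  if (x_norm$degenerate) stop_n2f("degenerate (constant) image")
  psnr(forward_pass(net, x_norm$pixels), x_norm$pixels, data_range = 1)
}

#' Replace targets by their ground-truth-corrected versions
#'
#' The chequerboard pair objective differs from a true Noise2Noise pair by
#' the signal term `s_b - s_a` (the clean-image difference between the two
#' downsamples). With known ground truth that term can be subtracted out
#' ("cheating"); for locally smooth images it is tiny, and training with
#' corrected targets measurably changes nothing -- the null result that
#' justifies ignoring it.
#'
#' @param pairs the 4 pairs from [build_training_set()].
#' @param clean the clean image in normalized space (matrix in \eqn{[0,1]},
#'   same shape as the noisy image the pairs came from).
#' @return pairs with each target `t` replaced by
#'   `clamp(t - (s_target - s_input), 0, 1)`.
#' @export
exact_correction_targets <- function(pairs, clean) {
  clean <- as_pixel_matrix(clean)
  up <- downsample_up(clean)
  lf <- downsample_left(clean)
  s <- list("up_even->up_odd" = list(a = up$even, b = up$odd),
            "up_odd->up_even" = list(a = up$odd, b = up$even),
            "left_even->left_odd" = list(a = lf$even, b = lf$odd),
            "left_odd->left_even" = list(a = lf$odd, b = lf$even))
  lapply(pairs, function(p) {
    sc <- s[[p$tag]]
    if (is.null(sc)) stop_n2f("unknown pair tag: ", p$tag)
    if (!all(dim(sc$b) == dim(p$target)))
      stop_n2f("clean image shape does not match the training pairs")
    p$target <- pmin(pmax(p$target - (sc$b - sc$a), 0), 1)
    p
  })
}

#' Denoise a single image by training on its own chequerboard downsamples
#'
#' The full pipeline: min-max normalize, build the four-pair chequerboard
#' training set, train the network one pair at a time with BCE loss and
#' Adam, validate every `validation_interval` iterations by how closely the
#' network maps the noisy image to itself, stop when validation has not
#' improved for `patience` checks (or at `max_iterations`), restore the
#' best-validation checkpoint, and return its output on the full image,
#' restored to the input's intensity scale.
#'
#' @param x the noisy image: numeric matrix or [image2d()].
#' @param net an [network_config()] describing the architecture.
#' @param control an [trainer_config()] with the training schedule.
#' @param downsampling `"chequerboard"` (the method), or `"block2"` /
#'   `"block3"` for the conventional k-fold block-downsampling ablation.
#' @param inference `"full"` applies the trained network to the whole noisy
#'   image; `"split"` applies it to the two "up" downsamples and
#'   reassembles them (ablation variant; needs an even number of columns).
#' @param reference optional clean ground-truth image of the same shape;
#'   when given, ground-truth PSNR is recorded at each validation (for
#'   studying the stopping rule -- never used by it).
#' @param exact_correction if `TRUE` (requires `reference`), train on
#'   ground-truth-corrected targets, see [exact_correction_targets()].
#' @return an object of class `noise2fast`; see [fitted.noise2fast()],
#'   [plot.noise2fast()] and friends.
#' @export
#' @examples
#' ph <- make_phantom("blobs", size = c(48, 48), seed = 1)
#' noisy <- add_gaussian_noise(ph$clean, sigma = 25, seed = 1)
#' fit <- noise2fast(noisy$noisy, net = network_config(block_widths = c(8, 16)),
#'                   control = trainer_config(max_iterations = 300,
#'                                            validation_interval = 50,
#'                                            patience = 2, seed = 1))
#' psnr(fitted(fit), ph$clean)
noise2fast <- function(x, net = network_config(), control = trainer_config(),
                       downsampling = c("chequerboard", "block2", "block3"),
                       inference = c("full", "split"),
                       reference = NULL, exact_correction = FALSE) {
  cl <- match.call()
  downsampling <- match.arg(downsampling)
  inference <- match.arg(inference)
  stopifnot(inherits(net, "n2f_config"), inherits(control, "n2f_control"))
  xm <- as_pixel_matrix(x)
  if (nrow(xm) < 2L || ncol(xm) < 2L) stop_n2f("image must be at least 2 x 2")
  if (!is.null(reference)) {
    reference <- as_pixel_matrix(reference)
    if (!all(dim(reference) == dim(xm)))
      stop_n2f("reference must match the image shape")
  }
  if (exact_correction && is.null(reference))
    stop_n2f("exact_correction requires a reference image")
  if (exact_correction && downsampling != "chequerboard")
    stop_n2f("exact_correction is defined for chequerboard pairs")

  xn <- normalize_image(xm)
  if (xn$degenerate) {
    trace <- list(losses = numeric(0),
                  validations = data.frame(iteration = integer(0),
                                           psnr = numeric(0),
                                           reference_psnr = numeric(0)),
                  best_iteration = 0L, stopped_reason = "degenerate_input")
    return(new_noise2fast(xm, xm, trace, NULL, xn, net, control,
                          downsampling, inference, cl))
  }

  pairs <- switch(downsampling,
                  chequerboard = build_training_set(xn),
                  block2 = block_training_set(xn$pixels, 2L),
                  block3 = block_training_set(xn$pixels, 3L))
  if (exact_correction) {
    ref_norm <- if (xn$scale > 0) (reference - xn$offset) / xn$scale else reference
    pairs <- exact_correction_targets(pairs, pmin(pmax(ref_norm, 0), 1))
  }

  network <- build_network(net, seed = control$seed)
  state <- adam_state(network)
  flat <- flatten_pairs(pairs)
  npairs <- length(pairs)
  order <- if (control$pair_sampling == "uniform_random") {
    with_seed(control$seed + 1L,
              sample.int(npairs, control$max_iterations, replace = TRUE))
  } else {
    rep_len(seq_len(npairs), control$max_iterations)
  }

  ref_range <- if (!is.null(reference)) diff(range(reference)) else NA_real_
  losses <- numeric(0)
  val_it <- integer(0); val_psnr <- numeric(0); val_ref <- numeric(0)
  best_psnr <- -Inf; best_iter <- 0L; best_weights <- network$weights
  stall <- 0L; done <- 0L
  stopped <- "max_iterations"

  while (done < control$max_iterations) {
    nstep <- min(control$validation_interval, control$max_iterations - done)
    res <- run_chunk(network, flat, order[(done + 1L):(done + nstep)],
                     control, state)
    network <- res$net; state <- res$state
    losses <- c(losses, res$losses)
    done <- done + nstep

    out_norm <- forward_pass(network, xn$pixels)
    v <- psnr(out_norm, xn$pixels, data_range = 1)
    val_it <- c(val_it, done); val_psnr <- c(val_psnr, v)
    if (!is.null(reference)) {
      val_ref <- c(val_ref, psnr(denormalize_image(xn, out_norm), reference,
                                 data_range = ref_range))
    }
    if (v > best_psnr) {
      best_psnr <- v; best_iter <- done
      best_weights <- network$weights
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) { stopped <- "patience"; break }
    }
  }

  network$weights <- best_weights
  out_norm <- forward_pass(network, xn$pixels)
  denoised <- if (inference == "full") {
    denormalize_image(xn, out_norm)
  } else {
    if (ncol(xm) %% 2L == 1L)
      stop_n2f("split inference needs an even number of columns")
    up <- downsample_up(xn$pixels)
    denormalize_image(xn, reassemble_up(forward_pass(network, up$even),
                                        forward_pass(network, up$odd)))
  }

  trace <- list(
    losses = losses,
    validations = data.frame(iteration = val_it, psnr = val_psnr,
                             reference_psnr = if (is.null(reference))
                               rep(NA_real_, length(val_it)) else val_ref),
    best_iteration = best_iter,
    stopped_reason = stopped)
  new_noise2fast(denoised, xm, trace, network, xn, net, control,
                 downsampling, inference, cl)
}

new_noise2fast <- function(denoised, input, trace, network, norm,
                           net_config, control, downsampling, inference, call) {
  structure(list(denoised = denoised, input = input, trace = trace,
                 network = network,
                 norm = list(offset = norm$offset, scale = norm$scale,
                             degenerate = norm$degenerate),
                 settings = list(net = net_config, control = control,
                                 downsampling = downsampling,
                                 inference = inference),
                 call = call),
            class = "noise2fast")
}
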