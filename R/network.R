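#' Architecture configuration for the denoising network
#'
#' The default network is deliberately small: for each block width, two
#' same-padded 3x3 convolutions with ReLU, the widths doubling block to
#' block (32, 64, 128, 256), then a single 1x1 convolution to one channel
#' followed by a logistic sigmoid. No batch normalization, no pooling, no
#' skip connections. The small capacity is a feature: the network overfits
#' the four-image training set quickly, and the validation rule catches the
#' peak before it does.
#'
#' @param in_channels number of input channels (denoising uses 1; each
#'   channel/frame of a multi-plane image is processed separately).
#' @param block_widths integer vector of channel widths, one per block.
#' @param convs_per_block convolutions per block.
#' @param kernel_size odd spatial kernel size of the body convolutions.
#' @param final_kernel_size odd kernel size of the single-channel head.
#' @return an object of class `n2f_config`.
#' @export
network_config <- function(in_channels = 1L,
                           block_widths = c(32L, 64L, 128L, 256L),
                           convs_per_block = 2L,
                           kernel_size = 3L,
                           final_kernel_size = 1L) {
  if (in_channels < 1L) stop_n2f("in_channels must be positive")
  if (length(block_widths) < 1L || any(block_widths < 1L))
    stop_n2f("block_widths must be positive integers")
  if (kernel_size %% 2L == 0L || final_kernel_size %% 2L == 0L)
    stop_n2f("kernel sizes must be odd")
  if (convs_per_block < 1L) stop_n2f("convs_per_block must be positive")
  structure(list(in_channels = as.integer(in_channels),
                 block_widths = as.integer(block_widths),
                 convs_per_block = as.integer(convs_per_block),
                 kernel_size = as.integer(kernel_size),
                 final_kernel_size = as.integer(final_kernel_size)),
            class = "n2f_config")
}

#' Side length of the receptive field
#'
#' Each same-padded `k x k` convolution grows the square of input pixels
#' one output pixel can depend on by `k - 1` per side, so the receptive
#' field extent is `1 + (kernel_size - 1) * convs_per_block * n_blocks +
#' (final_kernel_size - 1)` (17 for the defaults). Output pixel `(i, j)`
#' depends on input pixels within Chebyshev distance `(extent - 1) / 2`.
#'
#' @param config an [network_config()] object.
#' @return integer side length.
#' @export
receptive_field_extent <- function(config = network_config()) {
  stopifnot(inherits(config, "n2f_config"))
  as.integer(1L +
    (config$kernel_size - 1L) * config$convs_per_block *
      length(config$block_widths) +
    (config$final_kernel_size - 1L))
}

layer_plan <- function(config) {
  widths <- integer(0); ks <- integer(0)
  cin <- config$in_channels
  for (w in config$block_widths) {
    for (i in seq_len(config$convs_per_block)) {
      widths <- c(widths, w); ks <- c(ks, config$kernel_size)
    }
  }
  widths <- c(widths, 1L)
  ks <- c(ks, config$final_kernel_size)
  list(out = widths, kernel = ks)
}

#' Build a network with deterministic fan-in-scaled initialization
#'
#' Weights are drawn from a uniform distribution with limits
#' `sqrt(6 / fan_in)` (fan_in = `k^2 * c_in`) from a private RNG stream
#' seeded by `seed`; biases start at zero. The same seed always yields a
#' bit-identical parameter state.
#'
#' @param config an [network_config()] object.
#' @param seed integer initialization seed.
#' @return an object of class `n2f_network`: `config`, `seed`, and
#'   `weights` -- per layer a `(k^2 * c_in) x c_out` kernel matrix `W` and a
#'   length-`c_out` bias `b`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "n2f_config"))
  plan <- layer_plan(config)
  cin <- config$in_channels
  weights <- vector("list", length(plan$out))
  with_seed(seed, {
    for (l in seq_along(plan$out)) {
      k <- plan$kernel[l]; cout <- plan$out[l]
      fan_in <- k * k * cin
      lim <- sqrt(6 / fan_in)
      weights[[l]] <- list(
        W = matrix(runif(fan_in * cout, -lim, lim), fan_in, cout),
        b = numeric(cout),
        kernel = k)
      cin <- cout
    }
  })
  structure(list(config = config, seed = as.integer(seed), weights = weights),
            class = "n2f_network")
}

#' Total number of trainable parameters
#' @param net an `n2f_network`.
#' @return integer count of weights plus biases.
#' @export
n_parameters <- function(net) {
  stopifnot(inherits(net, "n2f_network"))
  sum(vapply(net$weights, function(l) length(l$W) + length(l$b), 0))
}

#' @export
print.n2f_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<n2f_network: %d conv layers, widths [%s], RF %d, %s parameters>\n",
              length(x$weights), paste(cfg$block_widths, collapse = ", "),
              receptive_field_extent(cfg),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

net_W <- function(net) lapply(net$weights, `[[`, "W")
net_b <- function(net) lapply(net$weights, `[[`, "b")
net_k <- function(net) vapply(net$weights, `[[`, 0L, "kernel")

#' Apply the network to an image
#'
#' Shape-preserving forward pass: same (zero) padding throughout, ReLU
#' between layers and a logistic sigmoid at the end, so every output pixel
#' lies strictly in (0, 1) and depends only on input pixels within the
#' receptive field. Deterministic given the weights.
#'
#' @param net an `n2f_network`.
#' @param img numeric matrix (single channel) or `H x W x C` array matching
#'   `config$in_channels`, values expected in \eqn{[0,1]}.
#' @return numeric `H x W` matrix with values in (0, 1).
#' @export
forward_pass <- function(net, img) {
  stopifnot(inherits(net, "n2f_network"))
  cin <- net$config$in_channels
  if (is.matrix(img)) {
    if (cin != 1L) stop_n2f("network expects ", cin, " channels")
    check_matrix(img, "img")
    h <- nrow(img); w <- ncol(img)
    xflat <- matrix(as.vector(img), h * w, 1L)
  } else if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] != cin) stop_n2f("network expects ", cin, " channels")
    if (any(!is.finite(img))) stop_n2f("img contains non-finite values")
    h <- dim(img)[1]; w <- dim(img)[2]
    xflat <- matrix(as.vector(img), h * w, cin)
  } else stop_n2f("img must be a matrix or H x W x C array")
  .cpp_forward(xflat, h, w, net_W(net), net_b(net), net_k(net))
}

#' Save / load network weights
#'
#' Single-file checkpoint used for the trainer's best-checkpoint restore.
#' @param net an `n2f_network`.
#' @param path file path for the checkpoint.
#' @return `save_network` returns `path` invisibly; `load_network` the
#'   restored `n2f_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "n2f_network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "n2f_network")) stop_n2f("not a network checkpoint")
  net
}
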