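#' Chequerboard downsampling along the horizontal axis ("up" pair)
#'
#' Splits an image into its two chequerboard parity classes -- pixels where
#' `i + j` is even versus odd (0-based row/column indices) -- and compresses
#' each class horizontally: row order is preserved and the surviving pixels
#' in each row close ranks leftward, giving two `m x n/2` images. An odd
#' trailing column is cropped first. The two outputs are two independent
#' interleaved samplings of the same scene, which is what makes them usable
#' as a Noise2Noise-style input/target pair.
#'
#' @param x numeric matrix, at least 2 x 2.
#' @return list with matrices `even` and `odd`, each `m x floor(n/2)`.
#' @export
downsample_up <- function(x) {
  x <- as_pixel_matrix(x)
  m <- nrow(x); n <- ncol(x)
  if (m < 2L || n < 2L) stop_n2f("image must be at least 2 x 2")
  if (n %% 2L == 1L) { x <- x[, -n, drop = FALSE]; n <- n - 1L }
  ri <- seq(1L, m, 2L)  # rows with even 0-based index
  ro <- seq(2L, m, 2L)
  co <- seq(1L, n, 2L)  # columns with even 0-based index
  ce <- seq(2L, n, 2L)
  even <- matrix(0, m, n %/% 2L)
  odd <- matrix(0, m, n %/% 2L)
  even[ri, ] <- x[ri, co, drop = FALSE]  # (even row, even col): i+j even
  even[ro, ] <- x[ro, ce, drop = FALSE]  # (odd row, odd col):  i+j even
  odd[ri, ] <- x[ri, ce, drop = FALSE]
  odd[ro, ] <- x[ro, co, drop = FALSE]
  list(even = even, odd = odd)
}

#' Chequerboard downsampling along the vertical axis ("left" pair)
#'
#' The same parity split as [downsample_up()], but columns keep their order
#' and each column closes ranks upward, giving two `m/2 x n` images. An odd
#' trailing row is cropped first.
#'
#' @param x numeric matrix, at least 2 x 2.
#' @return list with matrices `even` and `odd`, each `floor(m/2) x n`.
#' @export
downsample_left <- function(x) {
  x <- as_pixel_matrix(x)
  m <- nrow(x); n <- ncol(x)
  if (m < 2L || n < 2L) stop_n2f("image must be at least 2 x 2")
  if (m %% 2L == 1L) { x <- x[-m, , drop = FALSE]; m <- m - 1L }
  ri <- seq(1L, m, 2L)
  ro <- seq(2L, m, 2L)
  cj <- seq(1L, n, 2L)  # even 0-based columns
  ck <- seq(2L, n, 2L)
  even <- matrix(0, m %/% 2L, n)
  odd <- matrix(0, m %/% 2L, n)
  even[, cj] <- x[ri, cj, drop = FALSE]
  even[, ck] <- x[ro, ck, drop = FALSE]
  odd[, cj] <- x[ro, cj, drop = FALSE]
  odd[, ck] <- x[ri, ck, drop = FALSE]
  list(even = even, odd = odd)
}

#' Invert the "up" chequerboard split
#'
#' Exact left inverse of [downsample_up()] on even-width images; also used
#' to reassemble per-downsample network outputs into a full-size image
#' (the "split" inference variant).
#'
#' @param even,odd matrices of identical shape `m x n/2`.
#' @return matrix of shape `m x n`.
#' @export
reassemble_up <- function(even, odd) {
  if (!all(dim(even) == dim(odd)))
    stop_n2f("even and odd halves must share a shape")
  m <- nrow(even); n <- 2L * ncol(even)
  ri <- seq(1L, m, 2L); ro <- seq(2L, m, 2L)
  co <- seq(1L, n, 2L); ce <- seq(2L, n, 2L)
  x <- matrix(0, m, n)
  x[ri, co] <- even[ri, , drop = FALSE]
  x[ro, ce] <- even[ro, , drop = FALSE]
  x[ri, ce] <- odd[ri, , drop = FALSE]
  x[ro, co] <- odd[ro, , drop = FALSE]
  x
}

#' Invert the "left" chequerboard split
#'
#' @param even,odd matrices of identical shape `m/2 x n`.
#' @return matrix of shape `m x n`.
#' @export
reassemble_left <- function(even, odd) {
  if (!all(dim(even) == dim(odd)))
    stop_n2f("even and odd halves must share a shape")
  m <- 2L * nrow(even); n <- ncol(even)
  ri <- seq(1L, m, 2L); ro <- seq(2L, m, 2L)
  cj <- seq(1L, n, 2L); ck <- seq(2L, n, 2L)
  x <- matrix(0, m, n)
  x[ri, cj] <- even[, cj, drop = FALSE]
  x[ro, ck] <- even[, ck, drop = FALSE]
  x[ro, cj] <- odd[, cj, drop = FALSE]
  x[ri, ck] <- odd[, ck, drop = FALSE]
  x
}

#' Build the four-pair chequerboard training set
#'
#' The whole training set the denoiser ever sees: the two "up" downsamples
#' mapped to each other in both directions, and likewise the two "left"
#' downsamples. The set is materialized once; no pixels are re-sampled
#' during training.
#'
#' @param x an `n2f_normalized` image from [normalize_image()] (must not be
#'   degenerate), or a numeric matrix already in \eqn{[0,1]}.
#' @return list of 4 pairs, each `list(input, target, tag)` with tags
#'   `"up_even->up_odd"`, `"up_odd->up_even"`, `"left_even->left_odd"`,
#'   `"left_odd->left_even"`.
#' @export
build_training_set <- function(x) {
  if (inherits(x, "n2f_normalized")) {
    if (x$degenerate)
      stop_n2f("constant image: no training set can be built")
    x <- x$pixels
  }
  x <- as_pixel_matrix(x)
  up <- downsample_up(x)
  lf <- downsample_left(x)
  list(
    list(input = up$even, target = up$odd, tag = "up_even->up_odd"),
    list(input = up$odd, target = up$even, tag = "up_odd->up_even"),
    list(input = lf$even, target = lf$odd, tag = "left_even->left_odd"),
    list(input = lf$odd, target = lf$even, tag = "left_odd->left_even")
  )
}

#' Block downsampling (conventional k-fold subsampling)
#'
#' Divides the image into `k x k` blocks and extracts one sub-image per
#' within-block offset, the conventional alternative to the chequerboard
#' split used for the fourfold/ninefold ablation. Output `t = k*u + v + 1`
#' (offsets `u`, `v` in `0..k-1`) holds pixels `x(k*i + u, k*j + v)`;
#' trailing rows/columns are cropped to multiples of `k`.
#'
#' @param x numeric matrix with both sides at least `k`.
#' @param k block side, 2 or 3.
#' @return list of `k^2` matrices of shape `floor(m/k) x floor(n/k)`.
#' @export
block_downsample <- function(x, k) {
  x <- as_pixel_matrix(x)
  if (!k %in% c(2L, 3L)) stop_n2f("k must be 2 or 3")
  m <- k * (nrow(x) %/% k); n <- k * (ncol(x) %/% k)
  if (m < k || n < k) stop_n2f("image smaller than one ", k, " x ", k, " block")
  x <- x[seq_len(m), seq_len(n), drop = FALSE]
  out <- vector("list", k * k)
  for (u in 0:(k - 1L)) for (v in 0:(k - 1L)) {
    out[[k * u + v + 1L]] <- x[seq(u + 1L, m, k), seq(v + 1L, n, k), drop = FALSE]
  }
  out
}

#' Recombine [block_downsample()] outputs
#'
#' @param blocks list of `k^2` equally shaped matrices in the order produced
#'   by [block_downsample()].
#' @param k block side, 2 or 3.
#' @return matrix of shape `k*nrow x k*ncol`.
#' @export
reassemble_blocks <- function(blocks, k) {
  if (length(blocks) != k * k) stop_n2f("need k^2 blocks")
  h <- nrow(blocks[[1]]); w <- ncol(blocks[[1]])
  x <- matrix(0, k * h, k * w)
  for (u in 0:(k - 1L)) for (v in 0:(k - 1L)) {
    x[seq(u + 1L, k * h, k), seq(v + 1L, k * w, k)] <- blocks[[k * u + v + 1L]]
  }
  x
}

# Training pairs for the block-downsampling ablation: each sub-image is
# paired with its cyclic successor in both directions, so every sub-image
# appears as input and as target.
block_training_set <- function(x, k) {
  subs <- block_downsample(x, k)
  nk <- length(subs)
  pairs <- vector("list", 2L * nk)
  for (t in seq_len(nk)) {
    s <- t %% nk + 1L
    pairs[[2L * t - 1L]] <- list(input = subs[[t]], target = subs[[s]],
                                 tag = sprintf("block%d->block%d", t - 1L, s - 1L))
    pairs[[2L * t]] <- list(input = subs[[s]], target = subs[[t]],
                            tag = sprintf("block%d->block%d", s - 1L, t - 1L))
  }
  pairs
}
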