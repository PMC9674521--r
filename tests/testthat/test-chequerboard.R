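test_that("up/left downsamples match the enumerated parity classes", {
  x <- matrix(0:15, 4, 4, byrow = TRUE)
  up <- downsample_up(x)
  expect_equal(up$even, matrix(c(0, 2, 5, 7, 8, 10, 13, 15), 4, 2, byrow = TRUE))
  expect_equal(up$odd, matrix(c(1, 3, 4, 6, 9, 11, 12, 14), 4, 2, byrow = TRUE))
  lf <- downsample_left(x)
  expect_equal(lf$even, matrix(c(0, 5, 2, 7, 8, 13, 10, 15), 2, 4, byrow = TRUE))
  expect_equal(lf$odd, matrix(c(4, 1, 6, 3, 12, 9, 14, 11), 2, 4, byrow = TRUE))

  x2 <- matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE)  # [[a,b],[c,d]]
  u2 <- downsample_up(x2)
  expect_equal(u2$even, matrix(c(10, 40), 2, 1))  # a, d
  expect_equal(u2$odd, matrix(c(20, 30), 2, 1))   # b, c
  l2 <- downsample_left(x2)
  expect_equal(l2$even, matrix(c(10, 40), 1, 2))  # a, d
  expect_equal(l2$odd, matrix(c(30, 20), 1, 2))   # c, b

  k <- matrix(7, 5, 6)
  expect_true(all(downsample_up(k)$even == 7) && all(downsample_up(k)$odd == 7))
  expect_true(all(downsample_left(k)$even == 7) && all(downsample_left(k)$odd == 7))
})

test_that("downsampling agrees with the brute-force oracle and partitions pixels", {
  set.seed(NULL)
  for (case in 1:40) {
    m <- 2L + (case * 7L) %% 32L
    n <- 2L + (case * 11L) %% 46L
    x <- random_image(m, n, seed = 1000L + case)
    up <- downsample_up(x)
    ou <- oracle_up(x)
    expect_identical(up$even, ou$even)
    expect_identical(up$odd, ou$odd)
    lf <- downsample_left(x)
    ol <- oracle_left(x)
    expect_identical(lf$even, ol$even)
    expect_identical(lf$odd, ol$odd)
    # value-multiset conservation against the evenly cropped source
    xc <- x[, seq_len(2L * (n %/% 2L)), drop = FALSE]
    expect_identical(sort(c(up$even, up$odd)), sort(as.vector(xc)))
    xr <- x[seq_len(2L * (m %/% 2L)), , drop = FALSE]
    expect_identical(sort(c(lf$even, lf$odd)), sort(as.vector(xr)))
    # exact inversion on evenly sized support
    expect_identical(reassemble_up(up$even, up$odd), xc + 0)
    expect_identical(reassemble_left(lf$even, lf$odd), xr + 0)
  }
})

test_that("downsampling a ramp doubles the horizontal gradient (lattice distortion)", {
  x <- matrix(rep(0:9, each = 8), 8, 10)  # x(i, j) = j, 0-based
  up <- downsample_up(x)
  dif <- up$even[, -1, drop = FALSE] - up$even[, -ncol(up$even), drop = FALSE]
  expect_true(all(dif == 2))
  dif_o <- up$odd[, -1, drop = FALSE] - up$odd[, -ncol(up$odd), drop = FALSE]
  expect_true(all(dif_o == 2))
})

test_that("degenerate shapes are rejected", {
  expect_error(downsample_up(matrix(1:3, 3, 1)), "at least 2 x 2")
  expect_error(downsample_left(matrix(1:3, 1, 3)), "at least 2 x 2")
  expect_error(reassemble_up(matrix(0, 2, 2), matrix(0, 2, 3)), "share a shape")
})

test_that("block downsampling extracts strided offsets and recombines exactly", {
  x <- matrix(0:15, 4, 4, byrow = TRUE)
  b <- block_downsample(x, 2L)
  expect_equal(b[[1]], matrix(c(0, 2, 8, 10), 2, 2, byrow = TRUE))
  expect_equal(b[[2]], matrix(c(1, 3, 9, 11), 2, 2, byrow = TRUE))
  expect_equal(b[[3]], matrix(c(4, 6, 12, 14), 2, 2, byrow = TRUE))
  expect_equal(b[[4]], matrix(c(5, 7, 13, 15), 2, 2, byrow = TRUE))
  expect_identical(reassemble_blocks(b, 2L), x + 0)

  r <- matrix(as.double(0:35), 6, 6)
  b3 <- block_downsample(r, 3L)
  expect_length(b3, 9L)
  expect_true(all(vapply(b3, function(m) all(dim(m) == c(2L, 2L)), TRUE)))
  expect_identical(sort(unlist(b3)), sort(as.vector(r)) + 0)
  expect_identical(reassemble_blocks(b3, 3L), r + 0)

  k <- matrix(3, 7, 7)  # odd size: cropped to 6 x 6
  bk <- block_downsample(k, 2L)
  expect_true(all(vapply(bk, function(m) all(m == 3), TRUE)))
  expect_error(block_downsample(x, 4), "must be 2 or 3")
})

test_that("the training set is the four tagged chequerboard pairs", {
  x <- normalize_image(random_image(64, 64, seed = 9))
  ts <- build_training_set(x)
  expect_length(ts, 4L)
  expect_identical(vapply(ts, `[[`, "", "tag"),
                   c("up_even->up_odd", "up_odd->up_even",
                     "left_even->left_odd", "left_odd->left_even"))
  expect_identical(dim(ts[[1]]$input), c(64L, 32L))
  expect_identical(dim(ts[[3]]$input), c(32L, 64L))
  for (p in ts) expect_identical(dim(p$input), dim(p$target))
  # pairs 1 and 2 are each other's reverses
  expect_identical(ts[[1]]$input, ts[[2]]$target)
  expect_identical(ts[[1]]$target, ts[[2]]$input)
  # composition with normalization matches the enumerated split
  y <- matrix(0:15, 4, 4, byrow = TRUE)
  tsn <- build_training_set(normalize_image(y))
  expect_equal(tsn[[1]]$input,
               matrix(c(0, 2, 5, 7, 8, 10, 13, 15), 4, 2, byrow = TRUE) / 15)
  expect_equal(tsn[[1]]$target,
               matrix(c(1, 3, 4, 6, 9, 11, 12, 14), 4, 2, byrow = TRUE) / 15)
  expect_error(build_training_set(normalize_image(matrix(5, 8, 8))),
               "constant image")
})
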