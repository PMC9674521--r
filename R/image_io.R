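#' Construct an image plane
#'
#' A thin wrapper around a numeric matrix carrying provenance metadata:
#' the storage type it came from and, for multi-frame or multi-channel
#' sources, which plane it is. Indices are 0-based.
#'
#' @param pixels numeric matrix of intensities, at least 2 x 2, all finite.
#' @param dtype storage type: `"uint8"`, `"uint16"` or `"float32"`.
#' @param frame,channel 0-based plane indices, or `NA` if not applicable.
#' @return an `image2d` object (a numeric matrix with attributes).
#' @export
image2d <- function(pixels, dtype = "float32", frame = NA_integer_,
                    channel = NA_integer_) {
  check_matrix(pixels, "pixels")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop_n2f("image must be at least 2 x 2 (got ",
             nrow(pixels), " x ", ncol(pixels), ")")
  dtype <- match.arg(dtype, c("uint8", "uint16", "float32"))
  structure(pixels, dtype = dtype, frame = frame, channel = channel,
            class = c("image2d", class(pixels)))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d, %s", nrow(x), ncol(x), attr(x, "dtype")))
  if (!is.na(attr(x, "frame"))) cat(", frame", attr(x, "frame"))
  if (!is.na(attr(x, "channel"))) cat(", channel", attr(x, "channel"))
  cat(sprintf(", range [%g, %g]>\n", min(x), max(x)))
  invisible(x)
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "image2d")) {
    attributes(x) <- list(dim = dim(x))
  }
  check_matrix(x)
  x
}

tiff_dtype <- function(info) {
  fmt <- info$sample.format
  bits <- info$bits.per.sample
  if (is.null(fmt)) fmt <- "uint"
  if (identical(fmt, "uint") && bits == 8L) return("uint8")
  if (identical(fmt, "uint") && bits == 16L) return("uint16")
  if (identical(fmt, "float") && bits == 32L) return("float32")
  stop_n2f("unsupported TIFF sample format: ", fmt, " ", bits, "-bit")
}

split_planes <- function(arr, dtype, frame) {
  if (length(dim(arr)) == 2L) {
    return(list(image2d(arr, dtype = dtype, frame = frame)))
  }
  lapply(seq_len(dim(arr)[3]) - 1L, function(ch) {
    image2d(arr[, , ch + 1L], dtype = dtype, frame = frame, channel = ch)
  })
}

#' Read a TIFF or PNG image into one matrix per plane
#'
#' Multi-page TIFFs yield one image per page (frame), multi-channel images
#' one per channel; every plane is returned as a separate [image2d()].
#' Integer samples are returned on their native integer scale (0..255 or
#' 0..65535) and float samples verbatim -- values are never clipped or
#' rescaled on read, so negative or out-of-range values in float data
#' survive untouched.
#'
#' @param path path to a TIFF (8/16-bit unsigned or 32-bit float, single- or
#'   multi-page) or PNG (8/16-bit) file.
#' @return list of [image2d()] planes, ordered frame-major then channel.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_n2f("cannot read '", path, "': no such file")
  magic <- readBin(path, "raw", 4L)
  is_png <- length(magic) == 4L &&
    identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))
  is_tif <- length(magic) >= 2L &&
    (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
     identical(magic[1:2], as.raw(c(0x4d, 0x4d))))
  if (is_png) return(read_png_planes(path))
  if (is_tif) return(read_tiff_planes(path))
  stop_n2f("'", path, "' is neither a TIFF nor a PNG file")
}

read_tiff_planes <- function(path) {
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)  # one row per page
  bits <- info$bits.per.sample
  fmt <- if (is.null(info$sample.format)) rep("uint", nrow(info))
         else info$sample.format
  dtypes <- vapply(seq_len(nrow(info)), function(p) {
    tiff_dtype(list(sample.format = fmt[p], bits.per.sample = bits[p]))
  }, "")
  any_float <- any(dtypes == "float32")
  pages <- if (any_float) {
    tiff::readTIFF(path, all = TRUE)
  } else {
    tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }
  if (!is.list(pages)) pages <- list(pages)
  out <- list()
  for (p in seq_along(pages)) {
    arr <- pages[[p]]
    storage.mode(arr) <- "double"
    if (any_float && dtypes[p] != "float32") {
      # integer pages read in scaled mode; restore native integer values
      arr <- round(arr * (2^bits[p] - 1))
    }
    frame <- if (length(pages) > 1L) p - 1L else NA_integer_
    out <- c(out, split_planes(arr, dtypes[p], frame))
  }
  out
}

read_png_planes <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  depth <- info$bit.depth
  if (!depth %in% c(8L, 16L))
    stop_n2f("unsupported PNG bit depth: ", depth)
  vals <- round(unclass(img) * (2^depth - 1))
  attributes(vals) <- list(dim = dim(img))
  split_planes(vals, if (depth == 8L) "uint8" else "uint16", NA_integer_)
}

#' Write one or more image planes to TIFF or PNG
#'
#' Integer targets are clipped to the type's range and rounded half to even;
#' `float32` values are written verbatim (never clipped), as uncompressed
#' IEEE-float TIFF. A list of planes becomes a multi-page TIFF. PNG output
#' supports `uint8` only.
#'
#' @param images a matrix/[image2d()] or a list of them (all the same shape).
#' @param path output path; extension picks the container (`.tif`/`.tiff`
#'   or `.png`).
#' @param dtype target storage type: `"uint8"`, `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(images, path, dtype = c("float32", "uint8", "uint16")) {
  dtype <- match.arg(dtype)
  if (!is.list(images)) images <- list(images)
  mats <- lapply(images, as_pixel_matrix)
  dims <- vapply(mats, dim, integer(2))
  if (length(mats) > 1L && any(dims != dims[, 1]))
    stop_n2f("all images must share the same shape")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (dtype != "uint8")
      stop_n2f("PNG output supports uint8 only; use a .tif path for ", dtype)
    if (length(mats) > 1L)
      stop_n2f("PNG output supports a single plane; use a .tif path")
    png::writePNG(clip_to_int(mats[[1]], 255) / 255, path)
    return(invisible(path))
  }
  if (dtype == "float32") {
    write_tiff_float32(mats, path)
  } else {
    maxv <- if (dtype == "uint8") 255 else 65535
    scaled <- lapply(mats, function(m) clip_to_int(m, maxv) / maxv)
    what <- if (length(scaled) == 1L) scaled[[1]] else scaled
    tiff::writeTIFF(what, path,
                    bits.per.sample = if (dtype == "uint8") 8L else 16L,
                    compression = "none")
  }
  invisible(path)
}

clip_to_int <- function(m, maxv) {
  round(pmin(pmax(m, 0), maxv))  # round() is half-to-even
}

# Minimal multi-page float32 TIFF writer (little-endian, uncompressed, one
# strip per page, SampleFormat = IEEE float). Written by hand because the
# tiff package only stores integer sample formats.
write_tiff_float32 <- function(mats, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)            # "II"
  writeBin(as.integer(42L), con, size = 2, endian = "little")
  # header IFD offset patched after layout is known
  offsets <- integer(0)
  pos <- 8L
  payload <- list()
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    nbytes <- 4L * length(m)
    strip_off <- pos
    ifd_off <- pos + nbytes
    payload[[k]] <- list(strip = strip_off, ifd = ifd_off, m = m)
    # IFD: 10 entries -> 2 + 10*12 + 4 bytes
    pos <- ifd_off + 2L + 10L * 12L + 4L
    offsets <- c(offsets, ifd_off)
  }
  writeBin(as.integer(offsets[1]), con, size = 4, endian = "little")
  ifd_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT, left-justified in the 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_along(payload)) {
    p <- payload[[k]]
    h <- nrow(p$m); w <- ncol(p$m)
    writeBin(as.vector(t(p$m)), con, size = 4, endian = "little")  # row-major
    writeBin(10L, con, size = 2, endian = "little")                # entry count
    ifd_entry(256L, 4L, 1L, w)                    # ImageWidth
    ifd_entry(257L, 4L, 1L, h)                    # ImageLength
    ifd_entry(258L, 3L, 1L, 32L)                  # BitsPerSample
    ifd_entry(259L, 3L, 1L, 1L)                   # Compression: none
    ifd_entry(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    ifd_entry(273L, 4L, 1L, p$strip)              # StripOffsets
    ifd_entry(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    ifd_entry(278L, 4L, 1L, h)                    # RowsPerStrip
    ifd_entry(279L, 4L, 1L, 4L * h * w)           # StripByteCounts
    ifd_entry(339L, 3L, 1L, 3L)                   # SampleFormat: IEEE float
    nxt <- if (k < length(payload)) payload[[k + 1]]$ifd else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Rescale an image to the unit interval
#'
#' Affine min-max rescaling used before training: the network ends in a
#' sigmoid and is trained with binary cross-entropy, so targets must lie in
#' \eqn{[0,1]}. The map is order-preserving and invertible, so raw values
#' (including negatives -- input data are never clipped) are restored
#' exactly by [denormalize_image()]. A constant image cannot be rescaled;
#' it is mapped to constant 0.5 and flagged `degenerate` so the trainer can
#' skip training and return the input unchanged.
#'
#' @param img numeric matrix or [image2d()].
#' @return an object of class `n2f_normalized`: list with `pixels` (matrix
#'   in \eqn{[0,1]}), `offset`, `scale` and logical `degenerate`.
#' @export
normalize_image <- function(img) {
  m <- as_pixel_matrix(img)
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    return(structure(list(pixels = matrix(0.5, nrow(m), ncol(m)),
                          offset = lo, scale = 0, degenerate = TRUE),
                     class = "n2f_normalized"))
  }
  structure(list(pixels = (m - lo) / (hi - lo),
                 offset = lo, scale = hi - lo, degenerate = FALSE),
            class = "n2f_normalized")
}

#' Undo [normalize_image()]
#'
#' @param norm an `n2f_normalized` object, or a matrix in \eqn{[0,1]}
#'   together with `offset`/`scale` taken from one (so network output can be
#'   restored to the input's intensity scale). No clipping is applied.
#' @param pixels optional replacement matrix in normalized space.
#' @return numeric matrix on the original intensity scale.
#' @export
denormalize_image <- function(norm, pixels = NULL) {
  if (!inherits(norm, "n2f_normalized"))
    stop_n2f("norm must come from normalize_image()")
  p <- if (is.null(pixels)) norm$pixels else pixels
  if (norm$degenerate) {
    return(matrix(norm$offset, nrow(p), ncol(p)))
  }
  p * norm$scale + norm$offset
}
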