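# Image and video-frame handling: containers, grayscale conversion, bilinear
# resize to the canonical face-crop resolution, frame-stream resampling, and
# file readers (PNG/JPEG via the png/jpeg packages, ASCII PGM/PPM, frame
# directories with an optional timestamps sidecar, CSV label manifests).

#' Canonical face-crop resolution
#'
#' All extractors consume face crops at one fixed resolution.  The pipeline
#' default is portrait 300 rows by 200 columns; face crops are taller than
#' wide.  Both numbers are configuration, not constants baked into any
#' algorithm: every function that needs the canonical size takes it as an
#' argument defaulting to this value.
#'
#' @return Integer vector `c(height, width)`.
#' @export
canonical_size <- function() c(300L, 200L)

#' RGB image container
#'
#' A 3-channel integer intensity image stored as an `height x width x 3`
#' array with values in \[0, 255\].
#'
#' @param pixels Numeric array `h x w x 3`, values in \[0, 255\].
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("rgb_image requires an h x w x 3 array (got %s channels)",
          if (is.array(pixels) && length(dim(pixels)) == 3L) dim(pixels)[3] else "non-array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) stopf("image dimensions must be >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("rgb_image intensities must lie in [0, 255]")
  structure(pixels, class = "rgb_image")
}

#' Grayscale image container
#'
#' @param pixels Numeric matrix `h x w`, values in \[0, 255\].
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stopf("gray_image requires a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stopf("image dimensions must be >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("gray_image intensities must lie in [0, 255]")
  structure(pixels, class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%g, %g]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d x 3>\n", d[1], d[2]))
  invisible(x)
}

#' @export
plot.gray_image <- function(x, ...) {
  m <- unclass(x)
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

#' Convert an RGB image to grayscale by channel averaging
#'
#' Each output pixel is the arithmetic mean of the three channel values,
#' rounded half-up to the nearest integer.
#'
#' @param image An [rgb_image].
#' @return A [gray_image] of the same height and width.
#' @export
to_grayscale <- function(image) {
  if (!inherits(image, "rgb_image")) {
    if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] != 3L)
      stopf("to_grayscale expects a 3-channel image (got %d channels)", dim(image)[3])
    image <- rgb_image(image)
  }
  m <- round_half_up((image[, , 1] + image[, , 2] + image[, , 3]) / 3)
  gray_image(matrix(m, nrow = dim(image)[1]))
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Pixel centers are aligned between source and target grids (the
#' half-pixel-center convention), with edge clamping.  A constant image is
#' reproduced exactly and outputs never leave the input's \[min, max\]
#' envelope.
#'
#' @param image A [gray_image] (or plain matrix).
#' @param target_h,target_w Target dimensions in pixels, both >= 1.
#' @return A [gray_image] of dimensions `target_h x target_w`.
#' @export
resize_bilinear <- function(image, target_h, target_w) {
  m <- unclass(image)
  if (!is.matrix(m) || nrow(m) < 1L || ncol(m) < 1L) stopf("empty image cannot be resized")
  if (target_h < 1L || target_w < 1L) stopf("target dimensions must be >= 1")
  h <- nrow(m); w <- ncol(m)
  if (h == target_h && w == target_w) return(gray_image(m))
  # source coordinate of each target pixel center (0-based)
  sy <- (seq_len(target_h) - 0.5) * h / target_h - 0.5
  sx <- (seq_len(target_w) - 0.5) * w / target_w - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(sx), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  top    <- m[y0 + 1L, x0 + 1L, drop = FALSE] * outer(1 - fy, 1 - fx) +
            m[y0 + 1L, x1 + 1L, drop = FALSE] * outer(1 - fy, fx)
  bottom <- m[y1 + 1L, x0 + 1L, drop = FALSE] * outer(fy, 1 - fx) +
            m[y1 + 1L, x1 + 1L, drop = FALSE] * outer(fy, fx)
  gray_image(top + bottom)
}

#' Resize a grayscale image to the canonical resolution
#'
#' @param image A [gray_image].
#' @param target_h,target_w Target size; defaults to [canonical_size()].
#' @return A [gray_image] at the canonical resolution.
#' @export
resize_canonical <- function(image,
                             target_h = canonical_size()[1],
                             target_w = canonical_size()[2]) {
  resize_bilinear(image, target_h, target_w)
}

#' Ordered frame stream
#'
#' @param frames List of [rgb_image] frames.
#' @param timestamps Numeric vector of seconds, strictly increasing, one per
#'   frame.
#' @param nominal_rate Nominal frame rate in frames/second.
#' @return An object of class `frame_stream`.
#' @export
frame_stream <- function(frames, timestamps, nominal_rate = NA_real_) {
  if (length(frames) != length(timestamps))
    stopf("frames and timestamps must have equal length")
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stopf("timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 nominal_rate = nominal_rate),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream: %d frames, %.3f-%.3f s, nominal %s fps>\n",
              length(x$frames),
              if (length(x$timestamps)) min(x$timestamps) else NA,
              if (length(x$timestamps)) max(x$timestamps) else NA,
              format(x$nominal_rate)))
  invisible(x)
}

#' @export
length.frame_stream <- function(x) length(x$frames)

#' Resample a frame stream to a fixed rate
#'
#' Places output ticks every `1/rate` seconds starting at the first input
#' timestamp and, for each tick, selects the input frame with the latest
#' timestamp at or before the tick (nearest-previous selection; no frame
#' interpolation, identification must use real frames).
#'
#' @param stream A [frame_stream].
#' @param rate Target rate in frames/second, > 0.
#' @return A [frame_stream] with `nominal_rate = rate`.  An empty stream
#'   resamples to an empty stream.
#' @export
resample_stream <- function(stream, rate) {
  stopifnot(inherits(stream, "frame_stream"))
  if (rate <= 0) stopf("resampling rate must be > 0")
  n <- length(stream$frames)
  if (n == 0L) return(frame_stream(list(), numeric(0), rate))
  t0 <- stream$timestamps[1]
  dur <- stream$timestamps[n] - t0
  # small tolerance so ticks landing on a frame time are not lost to rounding
  nticks <- floor(dur * rate + 1e-9) + 1L
  ticks <- t0 + (seq_len(nticks) - 1L) / rate
  idx <- findInterval(ticks + 1e-9, stream$timestamps)
  frame_stream(stream$frames[idx], ticks, rate)
}

# ---------------------------------------------------------------------------
# file I/O

#' Read a single image file
#'
#' Supports PNG and JPEG (via the png/jpeg packages) and ASCII netpbm
#' (P2 grayscale, P3 color).  Returns an [rgb_image]; grayscale sources are
#' replicated across channels.
#'
#' @param path Image file path.
#' @return An [rgb_image].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    a <- jpeg::readJPEG(path)
  } else if (ext %in% c("pgm", "ppm", "pnm")) {
    return(read_pnm(path))
  } else stopf("unsupported image format: %s", path)
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  rgb_image(round_half_up(a * 255))
}

#' Write a grayscale or RGB image as PNG
#'
#' @param image A [gray_image] or [rgb_image].
#' @param path Destination path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

# ASCII netpbm (P2/P3) reader: text-only image fixtures need no binary codec
read_pnm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- tok[1]
  if (!magic %in% c("P2", "P3")) stopf("only ASCII P2/P3 netpbm supported: %s", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) * 255 / maxv
  if (magic == "P2") {
    m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    rgb_image(array(rep(m, 3L), dim = c(h, w, 3L)))
  } else {
    a <- aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L))
    rgb_image(a)
  }
}

#' Read a label manifest
#'
#' A manifest is a CSV with columns `image_path` and `identity_id` (and an
#' optional `split`).  Relative image paths are resolved against the
#' manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with absolute `image_path`, `identity_id` (character)
#'   and `split` (possibly `NA`).
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "identity_id") %in% names(df)))
    stopf("manifest must have columns image_path, identity_id: %s", path)
  root <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$image_path), df$image_path,
                file.path(root, df$image_path))
  data.frame(image_path = abs,
             identity_id = as.character(df$identity_id),
             split = if ("split" %in% names(df)) df$split else NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a frame directory as a frame stream
#'
#' Video arrives as a directory of zero-padded numerically named image files
#' (codec independence).  An optional `timestamps.csv` sidecar with columns
#' `frame_index`, `time_s` supplies timing; otherwise frames are assumed
#' evenly spaced at `default_rate`.
#'
#' @param dir Directory of frames.
#' @param default_rate Rate assumed when no timestamps sidecar exists.
#' @return A [frame_stream].
#' @export
read_frame_dir <- function(dir, default_rate = 10) {
  files <- list.files(dir, pattern = "\\.(png|jpe?g|pgm|ppm)$", full.names = TRUE)
  files <- files[order(basename(files))]
  frames <- lapply(files, read_image)
  ts_path <- file.path(dir, "timestamps.csv")
  if (file.exists(ts_path)) {
    ts <- utils::read.csv(ts_path)
    if (nrow(ts) != length(frames))
      stopf("timestamps.csv has %d rows for %d frames", nrow(ts), length(frames))
    timestamps <- ts$time_s[order(ts$frame_index)]
    rate <- if (length(timestamps) > 1L) 1 / stats::median(diff(timestamps)) else default_rate
  } else {
    timestamps <- (seq_along(frames) - 1L) / default_rate
    rate <- default_rate
  }
  frame_stream(frames, timestamps, rate)
}
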