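#' Image stack container
#'
#' Lightweight container for a single-channel acquisition: a 2D field
#' (`y` x `x` matrix) or a 3D z- or time-stack (`z|t` x `y` x `x` array),
#' together with the physical pixel size, the camera bit depth and, for
#' time series, the frame interval. Pixel values are arbitrary intensity
#' units: integers in `[0, 2^bit_depth - 1]` straight off the camera,
#' unbounded non-negative reals after correction stages.
#'
#' @param pixels numeric matrix `(y, x)` or array `(z|t, y, x)`, non-negative.
#' @param channel_name channel label, e.g. `"647"`.
#' @param pixel_size_um micrometres per pixel, > 0.
#' @param bit_depth integer, 8 or 16.
#' @param frame_interval_s seconds per frame for time series, or `NULL`.
#' @param corrected logical; `TRUE` once a correction stage has run.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(pixels, channel_name = "ch1", pixel_size_um = 1,
                        bit_depth = 16L, frame_interval_s = NULL,
                        corrected = FALSE) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stopf("pixels must be a 2D matrix or 3D array")
  if (any(pixels < 0)) stopf("pixel values must be non-negative")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  if (!is.null(frame_interval_s) && frame_interval_s <= 0)
    stopf("frame_interval_s must be > 0")
  if (!corrected && any(pixels > 2^bit_depth - 1))
    stopf("pixel values exceed 2^bit_depth - 1 for an uncorrected image")
  structure(
    list(pixels = pixels, channel_name = channel_name,
         pixel_size_um = pixel_size_um, bit_depth = as.integer(bit_depth),
         frame_interval_s = frame_interval_s, corrected = corrected),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack '%s': %s px, %d-bit, %.3f um/px%s%s\n",
              x$channel_name, paste(d, collapse = " x "), x$bit_depth,
              x$pixel_size_um,
              if (!is.null(x$frame_interval_s))
                sprintf(", dt = %g s", x$frame_interval_s) else "",
              if (isTRUE(x$corrected)) " (corrected)" else ""))
  invisible(x)
}

#' Number of frames/planes in a stack
#' @param x an `ImageStack`.
#' @return integer; 1 for a 2D field.
#' @export
n_frames <- function(x) {
  d <- dim(x$pixels)
  if (length(d) == 2L) 1L else d[1L]
}

#' Extract one plane of a stack as a 2D matrix
#' @param x an `ImageStack`.
#' @param i plane index.
#' @return numeric matrix `(y, x)`.
#' @export
get_frame <- function(x, i = 1L) {
  d <- dim(x$pixels)
  if (length(d) == 2L) {
    if (i != 1L) stopf("2D image has a single frame")
    return(x$pixels)
  }
  if (i < 1L || i > d[1L]) stopf("frame index %d out of range 1..%d", i, d[1L])
  matrix(x$pixels[i, , ], d[2L], d[3L])
}

#' Read a TIFF file into an ImageStack
#'
#' Single- or multi-page grayscale TIFF, 8 or 16 bit. Axes are normalized
#' to `(y, x)` for a single page and `(t/z, y, x)` for a multi-page file.
#' Pixel size and frame interval are not stored in plain TIFFs by the
#' acquisition software used here, so they are supplied by the caller.
#'
#' @param path path to a readable TIFF.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_s optional seconds per frame (time series).
#' @param channel_name channel label.
#' @return an `ImageStack`.
#' @export
read_image_stack <- function(path, pixel_size_um = 1, frame_interval_s = NULL,
                             channel_name = "ch1") {
  if (!file.exists(path)) stopf("cannot read TIFF: no such file '%s'", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stopf("cannot read TIFF '%s': %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(unlist(pages)) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L))
    stopf("unsupported TIFF sample format (%s bits) in '%s'", bits, path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first sample of multi-sample
    p
  })
  px <- if (length(pages) == 1L) {
    pages[[1L]]
  } else {
    arr <- array(0, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr
  }
  image_stack(px, channel_name = channel_name, pixel_size_um = pixel_size_um,
              bit_depth = as.integer(bits), frame_interval_s = frame_interval_s)
}

#' Write an ImageStack to a (multi-page) TIFF
#'
#' Values are stored at the stack's bit depth; uncorrected integer data
#' round-trip exactly through [read_image_stack()].
#'
#' @param x an `ImageStack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(x, path) {
  maxval <- 2^x$bit_depth - 1
  if (any(x$pixels > maxval))
    stopf("pixel values exceed the %d-bit range; rescale before writing",
          x$bit_depth)
  frames <- lapply(seq_len(n_frames(x)), function(i) get_frame(x, i) / maxval)
  tiff::writeTIFF(frames, path, bits.per.sample = x$bit_depth,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Subtract a dark/background calibration frame
#'
#' Per-pixel difference, clipped at zero (downstream stages take means of
#' non-negative intensities). Background frames are per-channel; the frame
#' must match the image's `(y, x)` shape and is recycled across the planes
#' of a 3D stack.
#'
#' @param image an `ImageStack` (2D or 3D).
#' @param background an `ImageStack` holding a 2D background frame.
#' @return background-corrected `ImageStack` (flagged `corrected`).
#' @export
subtract_background_frame <- function(image, background) {
  bg <- if (inherits(background, "ImageStack")) background$pixels else background
  if (length(dim(bg)) != 2L) stopf("background must be a single 2D frame")
  d <- dim(image$pixels)
  yx <- if (length(d) == 2L) d else d[2:3]
  if (!all(dim(bg) == yx))
    stopf("background shape (%s) does not match image (%s)",
          paste(dim(bg), collapse = "x"), paste(yx, collapse = "x"))
  px <- image$pixels
  if (length(d) == 2L) {
    px <- pmax(px - bg, 0)
  } else {
    for (i in seq_len(d[1L])) px[i, , ] <- pmax(px[i, , ] - bg, 0)
  }
  out <- image
  out$pixels <- px
  out$corrected <- TRUE
  out
}
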