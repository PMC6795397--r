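#' Time-lapse grayscale frame stack
#'
#' Container for an ordered set of grayscale frames with a known frame rate,
#' the raw input of the contractility pipeline. Frames are numeric matrices
#' (rows = y downward, columns = x rightward) with intensities nominally in
#' \[0, 1\].
#'
#' @param frames list of numeric matrices, all the same size (>= 2 frames).
#' @param frame_rate acquisition rate in Hz (> 0).
#' @param pixel_size physical pixel size in micrometers per pixel, if known.
#'   The contractility trace is nondimensional, so the pipeline never
#'   requires it.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, pixel_size = NA_real_) {
  if (!is.list(frames) || length(frames) < 2L)
    stopf("`frames` must be a list of at least 2 matrices")
  if (!all(vapply(frames, is.matrix, logical(1))))
    stopf("every frame must be a numeric matrix")
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    stopf("frames differ in shape (first mismatch at frame %d)",
          which(!same)[1])
  if (!is_number(frame_rate) || frame_rate <= 0)
    stopf("frame_rate must be > 0")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack: %d frames of %d x %d px at %g Hz (%.2f s)\n",
              length(x$frames), d[1], d[2], x$frame_rate,
              length(x$frames) / x$frame_rate))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Frame acquisition times
#'
#' @param stack a [frame_stack()].
#' @return numeric vector of times in seconds, starting at 0.
#' @export
stack_times <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  (seq_along(stack$frames) - 1) / stack$frame_rate
}

#' Write a frame stack as a multi-page TIFF
#'
#' Intensities are clipped to \[0, 1\] on write.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, bits = 16) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!bits %in% c(8, 16)) stopf("bits must be 8 or 16")
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' Color pages are converted to grayscale by channel averaging.
#'
#' @param path TIFF file path.
#' @param frame_rate acquisition rate in Hz (TIFF files rarely carry it).
#' @param pixel_size optional pixel size in micrometers per pixel.
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path, frame_rate, pixel_size = NA_real_) {
  if (!file.exists(path)) stopf("input stack not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
    p
  })
  frame_stack(frames, frame_rate, pixel_size)
}
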