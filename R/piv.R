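#' PIV interrogation parameters
#'
#' Parameters for the windowed normalized cross-correlation displacement
#' search. The defaults (32 px windows, 50% overlap, three-point Gaussian
#' subpixel fit, 2 px median-residual validation) are standard PIV practice
#' for speckle imagery of this kind.
#'
#' @param window_size interrogation window side in pixels (>= 8).
#' @param overlap window overlap in pixels (`0 <= overlap < window_size`);
#'   grid spacing is `window_size - overlap`.
#' @param search_margin maximum displacement searched, in pixels. Windows
#'   without a full search margin inside the image are marked invalid rather
#'   than zero-padded, which avoids biased divergence at the edges.
#' @param subpixel subpixel peak estimator: `"gaussian3"` (three-point
#'   Gaussian, falling back to parabolic where the correlation is
#'   non-positive), `"parabolic"`, or `"none"`.
#' @param validation_threshold residual (px) against the median of the
#'   neighboring vectors above which a vector is declared an outlier and
#'   replaced by that neighbor median; `NULL` disables validation.
#' @return an object of class `piv_params`.
#' @export
piv_params <- function(window_size = 32, overlap = 16, search_margin = 6,
                       subpixel = c("gaussian3", "parabolic", "none"),
                       validation_threshold = 2) {
  subpixel <- match.arg(subpixel)
  if (!is_count(window_size, 8)) stopf("window_size must be an integer >= 8")
  if (!is_count(overlap, 0) || overlap >= window_size)
    stopf("need 0 <= overlap < window_size")
  if (!is_count(search_margin, 1)) stopf("search_margin must be >= 1")
  if (!is.null(validation_threshold) &&
      (!is_number(validation_threshold) || validation_threshold <= 0))
    stopf("validation_threshold must be > 0 or NULL")
  structure(list(window_size = as.integer(window_size),
                 overlap = as.integer(overlap),
                 search_margin = as.integer(search_margin),
                 subpixel = subpixel,
                 validation_threshold = validation_threshold),
            class = "piv_params")
}

subpixel_code <- function(subpixel) {
  switch(subpixel, none = 0L, gaussian3 = 1L, parabolic = 2L)
}

# median of valid neighbor vectors in the 3x3 neighborhood (center excluded);
# returns c(u, v) or c(NA, NA) when no valid neighbor exists
neighbor_median <- function(u, v, ok, iy, ix) {
  ny <- nrow(u); nx <- ncol(u)
  ii <- max(1L, iy - 1L):min(ny, iy + 1L)
  jj <- max(1L, ix - 1L):min(nx, ix + 1L)
  sel <- ok[ii, jj, drop = FALSE]
  sel[ii == iy, jj == ix] <- FALSE
  if (!any(sel)) return(c(NA_real_, NA_real_))
  c(median(u[ii, jj, drop = FALSE][sel]), median(v[ii, jj, drop = FALSE][sel]))
}

# median-test validation: outliers (residual vs neighbor median above the
# threshold) are replaced by the neighbor median and flagged `replaced`
validate_vectors <- function(u, v, valid, threshold) {
  replaced <- matrix(FALSE, nrow(u), ncol(u))
  if (is.null(threshold)) return(list(u = u, v = v, replaced = replaced))
  outlier <- matrix(FALSE, nrow(u), ncol(u))
  for (iy in seq_len(nrow(u))) {
    for (ix in seq_len(ncol(u))) {
      if (!valid[iy, ix]) next
      med <- neighbor_median(u, v, valid, iy, ix)
      if (any(is.na(med))) next
      if (sqrt((u[iy, ix] - med[1])^2 + (v[iy, ix] - med[2])^2) > threshold)
        outlier[iy, ix] <- TRUE
    }
  }
  ok <- valid & !outlier
  for (iy in seq_len(nrow(u))) {
    for (ix in seq_len(ncol(u))) {
      if (!outlier[iy, ix]) next
      med <- neighbor_median(u, v, ok, iy, ix)
      if (any(is.na(med))) next  # no trustworthy neighbors: keep as measured
      u[iy, ix] <- med[1]; v[iy, ix] <- med[2]
      replaced[iy, ix] <- TRUE
    }
  }
  list(u = u, v = v, replaced = replaced)
}

#' Construct a displacement field
#'
#' Builds a `displacement_field` from its components, for fields measured
#' elsewhere or constructed analytically. [piv_displacement()] produces the
#' same structure.
#'
#' @param grid_x,grid_y window-center coordinates in pixels (strictly
#'   increasing, uniform spacing).
#' @param u,v displacement component matrices in px
#'   (`length(grid_y)` x `length(grid_x)`; row = y grid, col = x grid).
#' @param valid logical matrix of usable windows (default: where `u` and
#'   `v` are finite).
#' @param replaced logical matrix of vectors filled in by validation
#'   (default: none).
#' @param t acquisition time in seconds.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(grid_x, grid_y, u, v, valid = NULL,
                               replaced = NULL, t = NA_real_) {
  if (!is.matrix(u) || !is.matrix(v) || !identical(dim(u), dim(v)))
    stopf("u and v must be matrices of identical size")
  if (nrow(u) != length(grid_y) || ncol(u) != length(grid_x))
    stopf("u must be length(grid_y) x length(grid_x)")
  if (is.null(valid)) valid <- is.finite(u) & is.finite(v)
  if (is.null(replaced)) replaced <- matrix(FALSE, nrow(u), ncol(u))
  structure(list(grid_x = as.numeric(grid_x), grid_y = as.numeric(grid_y),
                 u = u, v = v, valid = valid, replaced = replaced, t = t),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "displacement_field: %d x %d windows (%d valid, %d replaced)%s\n",
    nrow(x$u), ncol(x$u), sum(x$valid), sum(x$replaced),
    if (is.finite(x$t)) sprintf(", t = %.3f s", x$t) else ""))
  invisible(x)
}

#' PIV displacement between two images
#'
#' Estimates the displacement field from `reference` to `frame` on a regular
#' grid of interrogation windows. Each window of the reference is compared
#' against shifted windows of `frame` within `search_margin` pixels by
#' zero-mean normalized cross-correlation (robust to illumination drift);
#' the correlation peak is refined to subpixel precision. Flat
#' (zero-variance) windows and windows lacking the full search margin are
#' marked invalid; vectors failing the neighbor-median validation are
#' replaced by the median of their valid neighbors and flagged `replaced`
#' (the replacement remains usable downstream).
#'
#' Window centers are reported in pixel coordinates (origin at the image
#' top-left, x rightward along columns, y downward along rows; pixel `(i, j)`
#' is centered at `x = j`, `y = i`, so a window covering columns
#' `j0 ... j0+W-1` has center `j0 + (W-1)/2`).
#'
#' @param reference,frame numeric matrices of identical size, each dimension
#'   larger than `window_size + 2 * search_margin`.
#' @param params a [piv_params()].
#' @return a `displacement_field`: window-center coordinates `grid_x`,
#'   `grid_y`, displacement matrices `u`, `v` (px, row = y grid, col = x
#'   grid), logical `valid` and `replaced` masks, and a time slot `t`.
#' @export
#' @examples
#' tex <- make_speckle_texture(96, 96, 500, seed = 3)
#' shifted <- rbind(tex[-(1:2), ], tex[1:2, ])  # circular shift 2 px up
#' f <- piv_displacement(tex, shifted, piv_params(window_size = 16,
#'                                                overlap = 8))
piv_displacement <- function(reference, frame, params = piv_params()) {
  stopifnot(inherits(params, "piv_params"))
  if (!is.matrix(reference) || !is.matrix(frame))
    stopf("reference and frame must be numeric matrices")
  if (!identical(dim(reference), dim(frame)))
    stopf("reference and frame must have identical dimensions")
  need <- params$window_size + 2 * params$search_margin
  if (nrow(reference) < need || ncol(reference) < need)
    stopf("image (%d x %d) too small: need at least %d px per side",
          nrow(reference), ncol(reference), need)
  raw <- ncc_grid_cpp(reference, frame, params$window_size, params$overlap,
                      params$search_margin, subpixel_code(params$subpixel))
  val <- validate_vectors(raw$u, raw$v, raw$valid,
                          params$validation_threshold)
  displacement_field(raw$grid_x, raw$grid_y, val$u, val$v, raw$valid,
                     val$replaced)
}

#' Mean speed between consecutive frames
#'
#' Runs PIV on every consecutive frame pair and returns the spatial mean of
#' the displacement magnitude (px/frame) over valid windows: entry `k` is the
#' mean speed between frames `k` and `k + 1`. Used to locate the quiescent
#' diastolic phase.
#'
#' @param stack a [frame_stack()] (>= 2 frames).
#' @param params a [piv_params()].
#' @return numeric vector of length `n_frames - 1`.
#' @export
consecutive_speed_trace <- function(stack, params = piv_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  vapply(seq_len(n - 1L), function(k) {
    f <- piv_displacement(stack$frames[[k]], stack$frames[[k + 1L]], params)
    use <- f$valid
    if (!any(use))
      stopf("no valid interrogation window between frames %d and %d", k,
            k + 1L)
    mean(sqrt(f$u[use]^2 + f$v[use]^2))
  }, numeric(1))
}

#' Select the diastolic reference frame
#'
#' Picks the frame with minimal cell velocity: for each frame a centered
#' two-sided speed is formed from the consecutive-pair speeds to its previous
#' and next frames (one-sided at the stack ends), and the frame minimizing it
#' is returned. Ties break to the smallest index, so a fully static video
#' yields frame 1.
#'
#' @param stack a [frame_stack()].
#' @param params a [piv_params()].
#' @param speeds optional precomputed [consecutive_speed_trace()] (avoids
#'   recomputation when the caller already has it).
#' @return integer frame index (1-based).
#' @export
select_reference_frame <- function(stack, params = piv_params(),
                                   speeds = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(speeds)) speeds <- consecutive_speed_trace(stack, params)
  n <- length(stack$frames)
  stopifnot(length(speeds) == n - 1L)
  centered <- vapply(seq_len(n), function(k) {
    if (k == 1L) speeds[1] else if (k == n) speeds[n - 1L]
    else (speeds[k - 1L] + speeds[k]) / 2
  }, numeric(1))
  which.min(centered)
}

#' Displacement fields relative to a fixed reference frame
#'
#' Computes one displacement field per frame, each against the single
#' diastolic reference frame, with the frame's acquisition time attached.
#' The field at the reference frame itself is identically zero.
#'
#' @param stack a [frame_stack()].
#' @param ref_index reference frame index (1-based), typically from
#'   [select_reference_frame()].
#' @param params a [piv_params()].
#' @return list of `displacement_field` objects, one per frame.
#' @export
displacement_series <- function(stack, ref_index, params = piv_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (!is_count(ref_index, 1) || ref_index > n)
    stopf("ref_index must be in 1..%d", n)
  ref <- stack$frames[[ref_index]]
  tt <- stack_times(stack)
  lapply(seq_len(n), function(k) {
    f <- piv_displacement(ref, stack$frames[[k]], params)
    f$t <- tt[k]
    f
  })
}

#' Write displacement fields as CSV
#'
#' Long-format export with one row per interrogation window and frame:
#' columns `t`, `grid_x`, `grid_y`, `u`, `v`, `valid`.
#'
#' @param fields list of `displacement_field`s (e.g. from
#'   [displacement_series()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(fields, path) {
  rows <- lapply(fields, function(f) {
    data.frame(t = f$t,
               grid_x = rep(f$grid_x, each = length(f$grid_y)),
               grid_y = rep(f$grid_y, times = length(f$grid_x)),
               u = as.vector(f$u), v = as.vector(f$v),
               valid = as.vector(f$valid))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
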