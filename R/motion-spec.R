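#' Prescribed contraction motion for synthetic beating videos
#'
#' A `motion_spec` describes a periodic, analytically known contraction
#' displacement field used to warp a static speckle texture into a synthetic
#' beating-monolayer video. Two field shapes are available:
#'
#' * `affine_contraction`: u(x, t) = -s(t) (x - center), a spatially uniform
#'   contraction towards `center` with divergence -2 s(t) = -a(t) everywhere,
#'   where a(t) is the amplitude waveform and s(t) = a(t) / 2. The waveform
#'   amplitude therefore *is* the peak absolute divergence.
#' * `radial_gaussian`: u(x, t) = -s(t) (x - center) exp(-r^2 / (2 sigma^2)),
#'   a localized contraction with closed-form divergence
#'   -s(t) (2 - r^2 / sigma^2) exp(-r^2 / (2 sigma^2)).
#'
#' The amplitude waveform a(t) is a raised sin^2 pulse (default) or triangle
#' pulse occupying the first `1 - rest_fraction` of each period, followed by a
#' quiescent diastolic rest phase, or an arbitrary sampled waveform. a(0) = 0:
#' recordings start at diastolic rest.
#'
#' @param kind `"affine_contraction"` or `"radial_gaussian"`.
#' @param width,height frame size in pixels (>= 64).
#' @param center contraction center, length-2 numeric `(x, y)` in pixel
#'   coordinates (pixel `(i, j)` sits at `x = j`, `y = i`). Default: frame
#'   center.
#' @param waveform `"sin2_pulse"`, `"triangle"`, or `"custom"`.
#' @param period beat period in seconds (> 0).
#' @param peak_divergence peak absolute divergence of the field
#'   (nondimensional, >= 0).
#' @param rest_fraction fraction of each cycle spent at zero amplitude
#'   (`0 <= rest_fraction < 1`).
#' @param frame_rate acquisition rate in Hz.
#' @param n_frames number of frames (>= 2).
#' @param sigma spatial scale of the `radial_gaussian` field in pixels.
#' @param samples for `waveform = "custom"`: amplitudes sampled uniformly
#'   over one period starting at t = 0; the first sample must be 0.
#'
#' @return an object of class `motion_spec`.
#' @seealso [analytic_displacement()], [render_beating_video()],
#'   [ground_truth_metrics()]
#' @export
#' @examples
#' spec <- motion_spec(n_frames = 40)
#' amplitude_at(spec, c(0, 0.25, 0.55))
motion_spec <- function(kind = c("affine_contraction", "radial_gaussian"),
                        width = 256, height = 256, center = NULL,
                        waveform = c("sin2_pulse", "triangle", "custom"),
                        period = 1.1, peak_divergence = 0.02,
                        rest_fraction = 0.3, frame_rate = 20,
                        n_frames = 200, sigma = 60, samples = NULL) {
  kind <- match.arg(kind)
  waveform <- match.arg(waveform)
  if (!is_count(width, 64) || !is_count(height, 64))
    stopf("width and height must be integers >= 64")
  if (!is_number(period) || period <= 0) stopf("period must be > 0")
  if (!is_number(peak_divergence) || peak_divergence < 0)
    stopf("peak_divergence must be >= 0")
  if (!is_number(rest_fraction) || rest_fraction < 0 || rest_fraction >= 1)
    stopf("rest_fraction must be in [0, 1)")
  if (!is_number(frame_rate) || frame_rate <= 0)
    stopf("frame_rate must be > 0")
  if (!is_count(n_frames, 2)) stopf("n_frames must be an integer >= 2")
  if (is.null(center)) center <- c((width + 1) / 2, (height + 1) / 2)
  if (!is.numeric(center) || length(center) != 2L || !all(is.finite(center)))
    stopf("center must be a finite length-2 numeric (x, y)")
  if (kind == "radial_gaussian" && (!is_number(sigma) || sigma <= 0))
    stopf("sigma must be > 0 for radial_gaussian")
  if (waveform == "custom") {
    if (is.null(samples) || !is.numeric(samples) || length(samples) < 2L)
      stopf("custom waveform needs a numeric `samples` vector (length >= 2)")
    if (abs(samples[1]) > .Machine$double.eps)
      stopf("custom waveform must start at 0 (diastolic rest at t = 0)")
  }
  structure(list(kind = kind, width = as.integer(width),
                 height = as.integer(height), center = as.numeric(center),
                 waveform = waveform, period = period,
                 peak_divergence = peak_divergence,
                 rest_fraction = rest_fraction, frame_rate = frame_rate,
                 n_frames = as.integer(n_frames), sigma = sigma,
                 samples = samples),
            class = "motion_spec")
}

#' @export
print.motion_spec <- function(x, ...) {
  cat(sprintf(
    "motion_spec: %s, %dx%d px, %s waveform\n  period %.3g s, peak divergence %.3g, rest fraction %.2g\n  %d frames at %g Hz (%.2f s)\n",
    x$kind, x$width, x$height, x$waveform, x$period, x$peak_divergence,
    x$rest_fraction, x$n_frames, x$frame_rate, x$n_frames / x$frame_rate))
  invisible(x)
}

# amplitude at cycle phase in [0, 1)
amp_at_phase <- function(spec, phase) {
  pw <- 1 - spec$rest_fraction
  a <- switch(spec$waveform,
    sin2_pulse = ifelse(phase < pw,
                        spec$peak_divergence * sin(pi * phase / pw)^2, 0),
    triangle   = ifelse(phase < pw,
                        spec$peak_divergence * (1 - abs(2 * phase / pw - 1)),
                        0),
    custom = {
      n <- length(spec$samples)
      xs <- seq(0, 1, length.out = n + 1L)
      approx(xs, c(spec$samples, spec$samples[1]), xout = phase)$y
    })
  a
}

#' Amplitude waveform of a motion specification
#'
#' Evaluates the (period-periodic) amplitude trace a(t). For
#' `affine_contraction` this equals the absolute divergence of the field at
#' time t.
#'
#' @param spec a [motion_spec()].
#' @param t times in seconds (vectorized).
#' @return numeric vector of amplitudes.
#' @export
amplitude_at <- function(spec, t) {
  stopifnot(inherits(spec, "motion_spec"))
  n <- t / spec$period
  amp_at_phase(spec, n - floor(n))
}

# displacement at arbitrary points without the inside-frame check; px, py
# numeric vectors, a = scalar amplitude
displacement_eval <- function(spec, px, py, a) {
  s <- a / 2
  dx <- px - spec$center[1]
  dy <- py - spec$center[2]
  if (spec$kind == "radial_gaussian") {
    g <- exp(-(dx^2 + dy^2) / (2 * spec$sigma^2))
    cbind(u = -s * dx * g, v = -s * dy * g)
  } else {
    cbind(u = -s * dx, v = -s * dy)
  }
}

#' Analytic ground-truth displacement field
#'
#' Evaluates the prescribed displacement u*(x, t) of a [motion_spec()] at a
#' set of points. This is the ground truth that the PIV stage is expected to
#' recover from rendered videos.
#'
#' @param spec a [motion_spec()].
#' @param points n x 2 matrix of `(x, y)` pixel coordinates inside the frame.
#' @param t a single time in seconds within the recording.
#' @return n x 2 matrix with columns `u`, `v` (pixels; x rightward, y
#'   downward).
#' @export
#' @examples
#' spec <- motion_spec(width = 128, height = 128, n_frames = 20)
#' analytic_displacement(spec, rbind(c(64.5, 64.5), c(74.5, 64.5)), 0.275)
analytic_displacement <- function(spec, points, t) {
  stopifnot(inherits(spec, "motion_spec"))
  points <- rbind(points)
  if (ncol(points) != 2L) stopf("points must be an n x 2 matrix")
  if (!is_number(t) || t < 0 || t > (spec$n_frames - 1) / spec$frame_rate)
    stopf("t must lie within the recording [0, %.3f] s",
          (spec$n_frames - 1) / spec$frame_rate)
  bad <- points[, 1] < 0.5 | points[, 1] > spec$width + 0.5 |
         points[, 2] < 0.5 | points[, 2] > spec$height + 0.5
  if (any(bad))
    stopf("%d point(s) fall outside the %d x %d frame", sum(bad),
          spec$width, spec$height)
  displacement_eval(spec, points[, 1], points[, 2], amplitude_at(spec, t))
}

# closed-form divergence at arbitrary points (no frame check)
divergence_eval <- function(spec, px, py, a) {
  s <- a / 2
  if (spec$kind == "radial_gaussian") {
    r2 <- (px - spec$center[1])^2 + (py - spec$center[2])^2
    -s * (2 - r2 / spec$sigma^2) * exp(-r2 / (2 * spec$sigma^2))
  } else {
    rep(-2 * s, length(px))
  }
}

#' Analytic ground-truth divergence
#'
#' Closed-form divergence of the prescribed displacement field at a set of
#' points: `-a(t)` everywhere for `affine_contraction`, and
#' `-s(t) (2 - r^2/sigma^2) exp(-r^2/(2 sigma^2))` for `radial_gaussian`.
#'
#' @inheritParams analytic_displacement
#' @return numeric vector of nondimensional divergence values.
#' @export
analytic_divergence <- function(spec, points, t) {
  stopifnot(inherits(spec, "motion_spec"))
  points <- rbind(points)
  divergence_eval(spec, points[, 1], points[, 2], amplitude_at(spec, t))
}

# spatial mean of |div| at unit amplitude: the trace is this constant times
# a(t) because the field is linear in s
spatial_divergence_factor <- function(spec, n_grid = 129) {
  if (spec$kind == "affine_contraction") return(1)
  xs <- seq(1, spec$width, length.out = n_grid)
  ys <- seq(1, spec$height, length.out = n_grid)
  g <- expand.grid(x = xs, y = ys)
  mean(abs(divergence_eval(spec, g$x, g$y, 1)))
}

#' Ground-truth contractility trace D*(t)
#'
#' Spatial average of the absolute analytic divergence over the frame at the
#' requested times. Because the field is linear in its amplitude, this equals
#' a constant spatial factor times a(t) (the factor is 1 for
#' `affine_contraction`).
#'
#' @param spec a [motion_spec()].
#' @param t times in seconds; default: the frame times of the recording.
#' @param n_grid grid resolution per axis for the spatial average
#'   (`radial_gaussian` only).
#' @return numeric vector D*(t), nondimensional.
#' @export
ground_truth_trace <- function(spec, t = NULL, n_grid = 129) {
  stopifnot(inherits(spec, "motion_spec"))
  if (is.null(t)) t <- (seq_len(spec$n_frames) - 1) / spec$frame_rate
  amplitude_at(spec, t) * spatial_divergence_factor(spec, n_grid)
}

#' Ground-truth beat metrics by dense sampling
#'
#' Computes the reference values of the beat metrics directly from the
#' analytic trace D*(t), sampled densely (default 10 kHz) over one period:
#' `D_peak` (maximum), `D_mean` (time average), `T_cycle` (the period) and
#' `T_contract` (time per cycle with D* above 10% of `D_peak`, the same
#' threshold convention as [compute_metrics()]).
#'
#' @param spec a [motion_spec()].
#' @param sample_rate dense sampling rate in Hz for the threshold integral.
#' @return list with `d_peak`, `d_mean`, `t_cycle`, `t_contract`.
#' @export
ground_truth_metrics <- function(spec, sample_rate = 1e4) {
  stopifnot(inherits(spec, "motion_spec"))
  tt <- seq(0, spec$period, by = 1 / sample_rate)
  tt <- tt[tt < spec$period]
  d <- ground_truth_trace(spec, tt)
  d_peak <- max(d)
  list(d_peak = d_peak,
       d_mean = mean(d),
       t_cycle = spec$period,
       t_contract = if (d_peak > 0) spec$period * mean(d > 0.1 * d_peak)
                    else 0)
}

#' Serialize a motion specification to YAML
#'
#' @param spec a [motion_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motion_spec <- function(spec, path) {
  stopifnot(inherits(spec, "motion_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a motion specification from YAML
#'
#' @param path YAML file written by [write_motion_spec()].
#' @return a [motion_spec()].
#' @export
read_motion_spec <- function(path) {
  x <- yaml::read_yaml(path)
  motion_spec(kind = x$kind, width = x$width, height = x$height,
              center = unlist(x$center), waveform = x$waveform,
              period = x$period, peak_divergence = x$peak_divergence,
              rest_fraction = x$rest_fraction, frame_rate = x$frame_rate,
              n_frames = x$n_frames,
              sigma = if (is.null(x$sigma)) 60 else x$sigma,
              samples = if (is.null(x$samples)) NULL else unlist(x$samples))
}
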