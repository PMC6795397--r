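#' Detect beats in a contractility trace
#'
#' Finds local maxima of D(t) with prominence at least
#' `min_prominence * max(D)` and pairwise separation at least
#' `min_separation` seconds (when two candidates are closer, the higher one
#' wins). Prominence is the standard topographic definition: peak height
#' minus the higher of the two minima separating it from the nearest taller
#' samples (or the trace ends). Plateau maxima report their first sample.
#'
#' The defaults suit monolayer beating at roughly 1 Hz: prominence 30% of
#' the trace maximum rejects noise ripple on the diastolic baseline, and
#' 0.4 s separation is well below physiological beat periods (~1 s and
#' longer) yet rules out double-counting a single contraction.
#'
#' @param trace a `contractility_trace` (length >= 3).
#' @param min_prominence required prominence as a fraction of `max(D)`.
#' @param min_separation minimum inter-peak separation in seconds.
#' @return integer vector of peak indices in time order (possibly empty).
#' @export
#' @examples
#' tt <- seq(0, 10 - 0.05, by = 0.05)
#' tr <- as_contractility_trace(tt, 0.02 * sin(pi * tt)^2)
#' tt[detect_beats(tr)]  # ~0.5, 1.5, ..., 9.5 s
detect_beats <- function(trace, min_prominence = 0.3, min_separation = 0.4) {
  stopifnot(inherits(trace, "contractility_trace"))
  D <- trace$D; tt <- trace$t
  if (length(D) < 3L) stopf("trace too short for peak detection (need >= 3)")
  if (!is_number(min_prominence) || min_prominence < 0)
    stopf("min_prominence must be >= 0")
  if (!is_number(min_separation) || min_separation < 0)
    stopf("min_separation must be >= 0")

  # local maxima on the run-length-compressed trace (plateau -> first index)
  r <- rle(D)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  cand <- integer(0)
  if (nr >= 3L) {
    for (k in 2:(nr - 1L)) {
      if (r$values[k] > r$values[k - 1L] && r$values[k] > r$values[k + 1L])
        cand <- c(cand, starts[k])
    }
  }
  if (length(cand) == 0L) return(integer(0))

  prominence <- vapply(cand, function(i) {
    h <- D[i]
    left <- if (i > 1L) {
      seg <- D[(i - 1L):1]
      higher <- which(seg > h)
      if (length(higher)) min(seg[1:higher[1]]) else min(seg)
    } else h
    right <- if (i < length(D)) {
      seg <- D[(i + 1L):length(D)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[1:higher[1]]) else min(seg)
    } else h
    h - max(left, right)
  }, numeric(1))

  keep <- cand[prominence >= min_prominence * max(D)]
  if (length(keep) == 0L) return(integer(0))

  # greedy separation: tallest first, drop anything too close to a kept peak
  ord <- keep[order(D[keep], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(tt[i] - tt[kept]) >= min_separation)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Contraction indicator H(t)
#'
#' Binary series marking when the monolayer is contracting: `H(t) = 1` where
#' `D(t) > 0.1 * d_peak` (strict inequality) and 0 otherwise.
#'
#' @param trace a `contractility_trace`.
#' @param d_peak peak contractility used for the threshold (> 0), normally
#'   the global `max(D)`.
#' @return a `contraction_indicator`: list with `t` and integer `H`.
#' @export
contraction_indicator <- function(trace, d_peak) {
  stopifnot(inherits(trace, "contractility_trace"))
  if (!is_number(d_peak) || d_peak <= 0) stopf("d_peak must be > 0")
  structure(list(t = trace$t, H = as.integer(trace$D > 0.1 * d_peak)),
            class = "contraction_indicator")
}

#' Chronotropic and inotropic beat metrics
#'
#' Summarizes a contractility trace into the standard beat parameters:
#'
#' * `d_peak`: global maximum of D(t) over the recording.
#' * `d_mean`: time average of D(t) over the full recording (rest phases
#'   included).
#' * `t_cycle`: mean inter-peak interval in seconds (`NA` with fewer than
#'   two peaks).
#' * `t_contract`: mean over beating cycles of the time with
#'   `D(t) > 0.1 * d_peak`, evaluated as a Riemann sum of the contraction
#'   indicator at the frame interval. Cycle boundaries are the midpoints
#'   between adjacent peaks; the first and last cycles are clipped to the
#'   recording.
#'
#' Per-beat peak times, peak values and contraction durations are reported
#' alongside the per-recording summaries.
#'
#' @param trace a nonempty `contractility_trace`.
#' @param peaks integer peak indices, normally from [detect_beats()]; at
#'   least one peak is required for the cycle metrics.
#' @return a `beat_metrics` object: list with `d_peak`, `d_mean`, `t_cycle`,
#'   `t_contract`, `n_beats` and a `per_beat` data.frame (`peak_time`,
#'   `peak_value`, `contraction_duration`).
#' @export
compute_metrics <- function(trace, peaks) {
  stopifnot(inherits(trace, "contractility_trace"))
  if (length(trace$D) == 0L) stopf("empty trace")
  peaks <- sort(as.integer(peaks))
  if (any(peaks < 1L | peaks > length(trace$D)))
    stopf("peak indices out of range")
  d_peak <- max(trace$D)
  d_mean <- mean(trace$D)
  dt <- 1 / trace$frame_rate
  n <- length(trace$D)

  t_cycle <- if (length(peaks) >= 2L) mean(diff(trace$t[peaks])) else NA_real_

  if (length(peaks) >= 1L && d_peak > 0) {
    H <- as.integer(trace$D > 0.1 * d_peak)
    # half-open cycles [b_i, b_{i+1}) with boundaries at inter-peak midpoints
    bounds <- c(trace$t[1],
                if (length(peaks) >= 2L)
                  (trace$t[peaks[-length(peaks)]] + trace$t[peaks[-1]]) / 2,
                trace$t[n] + dt)
    durations <- vapply(seq_len(length(bounds) - 1L), function(i) {
      inside <- trace$t >= bounds[i] & trace$t < bounds[i + 1L]
      sum(H[inside]) * dt
    }, numeric(1))
    t_contract <- mean(durations)
  } else {
    durations <- numeric(0)
    t_contract <- NA_real_
  }

  per_beat <- data.frame(
    peak_time = trace$t[peaks],
    peak_value = trace$D[peaks],
    contraction_duration = if (length(durations)) durations else numeric(0))

  structure(list(d_peak = d_peak, d_mean = d_mean, t_cycle = t_cycle,
                 t_contract = t_contract, n_beats = length(peaks),
                 per_beat = per_beat),
            class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  cat(sprintf(
    "beat_metrics: %d beats\n  D_peak = %.4g, D_mean = %.4g\n  T_cycle = %s s, T_contract = %s s\n",
    x$n_beats, x$d_peak, x$d_mean,
    if (is.na(x$t_cycle)) "NA" else sprintf("%.3f", x$t_cycle),
    if (is.na(x$t_contract)) "NA" else sprintf("%.3f", x$t_contract)))
  invisible(x)
}

#' Convert beat metrics to a one-row data frame
#'
#' @param x a `beat_metrics` object.
#' @param ... unused.
#' @return one-row data.frame with columns `d_peak`, `d_mean`, `t_cycle`,
#'   `t_contract`, `n_beats`.
#' @export
as.data.frame.beat_metrics <- function(x, ...) {
  data.frame(d_peak = x$d_peak, d_mean = x$d_mean, t_cycle = x$t_cycle,
             t_contract = x$t_contract, n_beats = x$n_beats)
}
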