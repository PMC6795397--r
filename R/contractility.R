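#' Divergence of a displacement field
#'
#' Computes div u = du/dx + dv/dy on the interrogation-window grid by central
#' differences, with the derivative step equal to the grid spacing in pixels
#' (displacements in px over distances in px, hence nondimensional). Central
#' differences are exact on affine fields, the natural regime for a
#' contracting monolayer at window scale. Cells whose four-point stencil
#' touches an invalid window are invalid, so the output loses a one-cell
#' border relative to the input grid.
#'
#' @param field a `displacement_field` from [piv_displacement()] (grid at
#'   least 3 x 3).
#' @return a `divergence_field`: `grid_x`, `grid_y` (interior window
#'   centers), `div` matrix (nondimensional), `valid` mask, `t`.
#' @export
divergence_field <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  ny <- length(field$grid_y); nx <- length(field$grid_x)
  if (ny < 3L || nx < 3L)
    stopf("grid too small for central differences: need >= 3 x 3 windows")
  hx <- diff(field$grid_x); hy <- diff(field$grid_y)
  if (max(abs(hx - hx[1])) > 1e-9 || max(abs(hy - hy[1])) > 1e-9)
    stopf("window grid spacing must be uniform")
  hx <- hx[1]; hy <- hy[1]
  ii <- 2:(ny - 1L); jj <- 2:(nx - 1L)
  dudx <- (field$u[ii, jj + 1L, drop = FALSE] -
           field$u[ii, jj - 1L, drop = FALSE]) / (2 * hx)
  dvdy <- (field$v[ii + 1L, jj, drop = FALSE] -
           field$v[ii - 1L, jj, drop = FALSE]) / (2 * hy)
  ok <- field$valid[ii, jj + 1L, drop = FALSE] &
        field$valid[ii, jj - 1L, drop = FALSE] &
        field$valid[ii + 1L, jj, drop = FALSE] &
        field$valid[ii - 1L, jj, drop = FALSE]
  d <- dudx + dvdy
  d[!ok] <- NA_real_
  structure(list(grid_x = field$grid_x[jj], grid_y = field$grid_y[ii],
                 div = d, valid = ok, t = field$t),
            class = "divergence_field")
}

#' Spatially averaged contractility of one divergence field
#'
#' Under the `"absolute"` convention (default throughout the package) this
#' is the mean of |div| over valid cells; under `"signed"` it is the mean of
#' -div, so that contraction (negative divergence) is positive. The absolute
#' convention is used for the trace D(t) because reported contractility
#' values are positive magnitudes of relative area change; the signed
#' variant is kept for diagnostics.
#'
#' @param divfield a `divergence_field` with at least one valid cell.
#' @param convention `"absolute"` or `"signed"`.
#' @return a nondimensional scalar.
#' @export
contractility_value <- function(divfield,
                                convention = c("absolute", "signed")) {
  stopifnot(inherits(divfield, "divergence_field"))
  convention <- match.arg(convention)
  use <- divfield$valid
  if (!any(use)) stopf("no valid divergence cell to average")
  if (convention == "absolute") mean(abs(divfield$div[use]))
  else mean(-divfield$div[use])
}

#' Contractility trace D(t)
#'
#' Converts a series of displacement fields (one per frame, relative to the
#' diastolic reference frame) into the temporal tracing of cellular
#' contractility: per frame, the divergence field is computed and spatially
#' averaged. D at the reference frame is 0 by construction, and D >= 0 under
#' the absolute convention.
#'
#' @param fields list of `displacement_field`s from [displacement_series()],
#'   on a common grid, with times attached.
#' @param convention `"absolute"` (default) or `"signed"`; see
#'   [contractility_value()].
#' @return a `contractility_trace`: data.frame-like list with `t` (s), `D`
#'   (nondimensional), `n_valid` (valid divergence cells per frame), plus
#'   the convention and the frame rate inferred from `t`.
#' @export
contractility_trace <- function(fields,
                                convention = c("absolute", "signed")) {
  convention <- match.arg(convention)
  if (length(fields) == 0) stopf("`fields` must be nonempty")
  divs <- lapply(fields, divergence_field)
  tt <- vapply(divs, function(d) d$t, numeric(1))
  D <- vapply(divs, contractility_value, numeric(1),
              convention = convention)
  nv <- vapply(divs, function(d) sum(d$valid), integer(1))
  fr <- if (length(tt) > 1L && all(is.finite(tt))) 1 / median(diff(tt))
        else NA_real_
  structure(list(t = tt, D = D, n_valid = nv, convention = convention,
                 frame_rate = fr),
            class = "contractility_trace")
}

#' Construct a contractility trace from raw values
#'
#' Builds a `contractility_trace` directly from a time base and D values,
#' for analyzing traces produced elsewhere (or analytic test signals) with
#' [detect_beats()] and [compute_metrics()].
#'
#' @param t times in seconds (uniformly spaced).
#' @param D contractility values, same length as `t`.
#' @param convention `"absolute"` or `"signed"`.
#' @param n_valid optional per-frame valid-cell counts.
#' @return a `contractility_trace`.
#' @export
as_contractility_trace <- function(t, D, convention = "absolute",
                                   n_valid = NA_integer_) {
  if (length(t) != length(D)) stopf("t and D must have equal length")
  fr <- if (length(t) > 1L) 1 / median(diff(t)) else NA_real_
  structure(list(t = as.numeric(t), D = as.numeric(D),
                 n_valid = rep_len(as.integer(n_valid), length(t)),
                 convention = convention, frame_rate = fr),
            class = "contractility_trace")
}

#' @export
print.contractility_trace <- function(x, ...) {
  cat(sprintf(
    "contractility_trace (%s): %d frames over %.2f s, max D = %.4g\n",
    x$convention, length(x$t), diff(range(x$t)), max(x$D)))
  invisible(x)
}

#' Cell-shortening trace
#'
#' Element-wise square root of the absolute-convention contractility trace,
#' interpretable as a linear measure of cardiomyocyte shortening during
#' contraction (the divergence measures relative area change, its square
#' root a relative length change).
#'
#' @param trace an absolute-convention `contractility_trace`.
#' @return numeric vector sqrt(D(t)).
#' @export
shortening_trace <- function(trace) {
  stopifnot(inherits(trace, "contractility_trace"))
  if (!identical(trace$convention, "absolute"))
    stopf("shortening is defined for the absolute convention only (signed averages may be negative)")
  sqrt(trace$D)
}

#' Write a contractility trace as CSV
#'
#' Columns `t`, `D`, `n_valid`.
#'
#' @param trace a `contractility_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "contractility_trace"))
  write.csv(data.frame(t = trace$t, D = trace$D, n_valid = trace$n_valid),
            path, row.names = FALSE)
  invisible(path)
}
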