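#' Random speckle texture
#'
#' Renders a static texture of Gaussian blobs, emulating the optical speckle
#' pattern (e.g. membrane-stain puncta in phase contrast) whose motion the
#' PIV stage tracks. Guaranteed nonuniform, intensities scaled to \[0, 1\],
#' deterministic for a fixed seed.
#'
#' @param width,height image size in pixels (>= 64).
#' @param n_speckles number of blobs (>= 1).
#' @param speckle_sigma blob standard deviation in pixels.
#' @param seed integer RNG seed.
#' @return a `height` x `width` numeric matrix in \[0, 1\].
#' @export
#' @examples
#' tex <- make_speckle_texture(128, 128, 800, 1.0, seed = 7)
#' var(as.vector(tex)) > 1e-4
make_speckle_texture <- function(width, height, n_speckles,
                                 speckle_sigma = 1.5, seed = 1) {
  if (!is_count(width, 64) || !is_count(height, 64))
    stopf("width and height must be integers >= 64")
  if (!is_count(n_speckles, 1)) stopf("n_speckles must be an integer >= 1")
  if (!is_number(speckle_sigma) || speckle_sigma <= 0)
    stopf("speckle_sigma must be > 0")
  img <- matrix(0, nrow = height, ncol = width)
  halo <- ceiling(4 * speckle_sigma)
  with_seed(seed, {
    cx <- runif(n_speckles, 0.5, width + 0.5)
    cy <- runif(n_speckles, 0.5, height + 0.5)
    amp <- runif(n_speckles, 0.5, 1)
    for (k in seq_len(n_speckles)) {
      j0 <- max(1L, floor(cx[k] - halo)); j1 <- min(width,  ceiling(cx[k] + halo))
      i0 <- max(1L, floor(cy[k] - halo)); i1 <- min(height, ceiling(cy[k] + halo))
      if (j0 > j1 || i0 > i1) next
      gx <- exp(-((j0:j1) - cx[k])^2 / (2 * speckle_sigma^2))
      gy <- exp(-((i0:i1) - cy[k])^2 / (2 * speckle_sigma^2))
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp[k] * outer(gy, gx)
    }
  })
  img / max(img)
}

# clamped interpolation of `tex` at fractional coordinates (xs, ys);
# method "bilinear" or "cubic" (Catmull-Rom)
sample_texture <- function(tex, xs, ys, method = "bilinear") {
  nr <- nrow(tex); nc <- ncol(tex)
  xs <- pmin(pmax(xs, 1), nc)
  ys <- pmin(pmax(ys, 1), nr)
  if (method == "bilinear") {
    x0 <- pmin(floor(xs), nc - 1L); y0 <- pmin(floor(ys), nr - 1L)
    fx <- xs - x0; fy <- ys - y0
    v00 <- tex[cbind(y0, x0)];       v01 <- tex[cbind(y0, x0 + 1L)]
    v10 <- tex[cbind(y0 + 1L, x0)];  v11 <- tex[cbind(y0 + 1L, x0 + 1L)]
    v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
      v10 * (1 - fx) * fy + v11 * fx * fy
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    # Catmull-Rom weights for offsets -1, 0, 1, 2
    cr <- function(f) list(
      ((-f + 2) * f - 1) * f / 2,
      ((3 * f - 5) * f^2 + 2) / 2,
      (((-3 * f + 4) * f + 1) * f) / 2,
      ((f - 1) * f^2) / 2)
    wx <- cr(fx); wy <- cr(fy)
    out <- 0
    for (a in 0:3) {
      row <- pmin(pmax(y0 + a - 1L, 1L), nr)
      acc <- 0
      for (b in 0:3) {
        col <- pmin(pmax(x0 + b - 1L, 1L), nc)
        acc <- acc + wx[[b + 1L]] * tex[cbind(row, col)]
      }
      out <- out + wy[[a + 1L]] * acc
    }
    out
  }
}

# inverse of the forward map x = X + u(X) at amplitude `a`, for output pixel
# coordinates (px, py): exact for the affine field, fixed point otherwise
inverse_map <- function(spec, px, py, a, iterations = 8L) {
  if (spec$kind == "affine_contraction") {
    s <- a / 2
    cbind(spec$center[1] + (px - spec$center[1]) / (1 - s),
          spec$center[2] + (py - spec$center[2]) / (1 - s))
  } else {
    X <- px; Y <- py
    for (i in seq_len(iterations)) {
      uv <- displacement_eval(spec, X, Y, a)
      X <- px - uv[, 1]; Y <- py - uv[, 2]
    }
    cbind(X, Y)
  }
}

#' Render a synthetic beating-monolayer video
#'
#' Warps a static speckle texture by the prescribed periodic contraction
#' field of a [motion_spec()] using inverse mapping (each output pixel looks
#' up the texture at its pre-image), then adds zero-mean Gaussian intensity
#' noise. At frames with zero amplitude and zero noise the output equals the
#' texture exactly, and when `period * frame_rate` is an integer, frames one
#' full period apart are bit-identical for `noise_sigma = 0` (the cycle phase
#' is computed by integer frame arithmetic, so no floating-point phase drift
#' accumulates).
#'
#' @param texture numeric matrix at least as large as the frame size of
#'   `spec`; larger textures are center-cropped.
#' @param spec a [motion_spec()].
#' @param noise_sigma standard deviation of the additive intensity noise
#'   (>= 0, on the \[0, 1\] intensity scale).
#' @param seed integer RNG seed for the noise.
#' @param interpolation `"bilinear"` (default) or `"cubic"` texture
#'   interpolation. Inverse mapping is used because forward splatting of
#'   texture pixels would leave holes.
#' @return a [frame_stack()] at the frame rate of `spec`.
#' @export
#' @examples
#' spec <- motion_spec(width = 128, height = 128, n_frames = 5,
#'                     period = 1, frame_rate = 20)
#' tex <- make_speckle_texture(128, 128, 500, seed = 2)
#' stack <- render_beating_video(tex, spec, noise_sigma = 0, seed = 1)
render_beating_video <- function(texture, spec, noise_sigma = 0.01, seed = 1,
                                 interpolation = c("bilinear", "cubic")) {
  stopifnot(inherits(spec, "motion_spec"))
  interpolation <- match.arg(interpolation)
  if (!is.matrix(texture)) stopf("texture must be a numeric matrix")
  if (!is_number(noise_sigma) || noise_sigma < 0)
    stopf("noise_sigma must be >= 0")
  if (nrow(texture) < spec$height || ncol(texture) < spec$width)
    stopf("texture (%d x %d) smaller than the %d x %d frame",
          nrow(texture), ncol(texture), spec$height, spec$width)
  off_r <- floor((nrow(texture) - spec$height) / 2)
  off_c <- floor((ncol(texture) - spec$width) / 2)
  crop <- texture[off_r + seq_len(spec$height), off_c + seq_len(spec$width),
                  drop = FALSE]

  px <- rep(seq_len(spec$width), each = spec$height)
  py <- rep(seq_len(spec$height), times = spec$width)

  m <- spec$period * spec$frame_rate
  integral_period <- abs(m - round(m)) < 1e-9

  amps <- vapply(seq_len(spec$n_frames), function(k) {
    if (integral_period) {
      amp_at_phase(spec, ((k - 1) %% round(m)) / round(m))
    } else {
      amplitude_at(spec, (k - 1) / spec$frame_rate)
    }
  }, numeric(1))

  # warp once per distinct amplitude so periodic frames are bit-identical
  warped <- new.env(parent = emptyenv())
  frames <- with_seed(seed, lapply(seq_len(spec$n_frames), function(k) {
    a <- amps[k]
    base <- if (a == 0) {
      crop
    } else {
      key <- sprintf("%.17g", a)
      if (is.null(warped[[key]])) {
        XY <- inverse_map(spec, px, py, a)  # in frame coordinates
        warped[[key]] <- matrix(
          sample_texture(texture, XY[, 1] + off_c, XY[, 2] + off_r,
                         interpolation),
          nrow = spec$height, ncol = spec$width)
      }
      warped[[key]]
    }
    if (noise_sigma > 0)
      base <- base + matrix(rnorm(length(base), 0, noise_sigma),
                            nrow = spec$height)
    base
  }))
  frame_stack(frames, spec$frame_rate)
}

#' Simulate a Cq table
#'
#' Draws per-sample Cq (quantification-cycle) values around specified group
#' means, emulating the already-normalized per-group qPCR summaries used for
#' relative quantification. Deterministic for a fixed seed. With a control
#' assay specified, the table carries matched target/control rows per sample
#' so the full per-sample delta-Ct path ([normalize_dct()]) is exercised.
#'
#' @param group_means named numeric vector: mean Cq per group for the target
#'   assay. Negative Cq values are permitted (pre-normalized scales).
#' @param sd between-sample standard deviation in cycles (>= 0).
#' @param n_per_group samples per group (>= 1).
#' @param seed integer RNG seed.
#' @param assay target assay label.
#' @param control_means optional named numeric vector (same groups, recycled
#'   if length 1): mean Cq of an endogenous-control assay; adds matched
#'   control rows.
#' @param control_sd standard deviation for the control assay.
#' @return data.frame with columns `sample_id`, `group`, `assay`, `cq`.
#' @export
#' @examples
#' simulate_cq_table(c(ctl = 9.46, hlhs = 7.17), sd = 0, n_per_group = 3,
#'                   seed = 1)
simulate_cq_table <- function(group_means, sd, n_per_group, seed = 1,
                              assay = "target", control_means = NULL,
                              control_sd = sd) {
  if (length(group_means) == 0 || is.null(names(group_means)) ||
      any(!nzchar(names(group_means))))
    stopf("group_means must be a nonempty named numeric vector")
  if (!is.numeric(group_means) || any(!is.finite(group_means)))
    stopf("group_means must be finite")
  if (!is_number(sd) || sd < 0) stopf("sd must be >= 0")
  if (!is_count(n_per_group, 1)) stopf("n_per_group must be an integer >= 1")
  groups <- names(group_means)
  if (!is.null(control_means)) {
    if (length(control_means) == 1L && is.null(names(control_means)))
      control_means <- setNames(rep(control_means, length(groups)), groups)
    if (!all(groups %in% names(control_means)))
      stopf("control_means must name every group")
  }
  with_seed(seed, {
    rows <- lapply(groups, function(g) {
      ids <- sprintf("%s_%02d", g, seq_len(n_per_group))
      out <- data.frame(sample_id = ids, group = g, assay = assay,
                        cq = rnorm(n_per_group, group_means[[g]], sd),
                        stringsAsFactors = FALSE)
      if (!is.null(control_means)) {
        out <- rbind(out, data.frame(
          sample_id = ids, group = g, assay = "control",
          cq = rnorm(n_per_group, control_means[[g]], control_sd),
          stringsAsFactors = FALSE))
      }
      out
    })
    do.call(rbind, rows)
  })
}

#' Write a complete synthetic dataset
#'
#' Renders a beating video and writes it together with its analytic ground
#' truth: the video as multi-page TIFF, the trace D*(t) as CSV (columns `t`,
#' `D_star`), the dense-sampling reference metrics as JSON, and the motion
#' specification as YAML.
#'
#' @param spec a [motion_spec()].
#' @param dir output directory (created if missing).
#' @param noise_sigma,seed,interpolation passed to [render_beating_video()].
#' @param n_speckles,speckle_sigma texture parameters
#'   ([make_speckle_texture()]; the texture seed is derived from `seed`).
#' @param bits TIFF bit depth.
#' @return invisibly, a named list of the written file paths.
#' @export
write_synthetic_dataset <- function(spec, dir, noise_sigma = 0.01, seed = 1,
                                    interpolation = "bilinear",
                                    n_speckles = 2000, speckle_sigma = 1.5,
                                    bits = 16) {
  stopifnot(inherits(spec, "motion_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tex <- make_speckle_texture(spec$width, spec$height, n_speckles,
                              speckle_sigma, seed = seed + 1)
  stack <- render_beating_video(tex, spec, noise_sigma, seed, interpolation)
  paths <- list(video = file.path(dir, "video.tif"),
                truth_trace = file.path(dir, "ground_truth_trace.csv"),
                truth_metrics = file.path(dir, "ground_truth_metrics.json"),
                spec = file.path(dir, "motion_spec.yaml"))
  write_frame_stack(stack, paths$video, bits = bits)
  tt <- stack_times(stack)
  write.csv(data.frame(t = tt, D_star = ground_truth_trace(spec, tt)),
            paths$truth_trace, row.names = FALSE)
  jsonlite::write_json(ground_truth_metrics(spec), paths$truth_metrics,
                       auto_unbox = TRUE, digits = NA)
  write_motion_spec(spec, paths$spec)
  invisible(paths)
}
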