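# Independent oracles used across test files. These deliberately take a
# different computational route from the package (whole-image FFT
# correlation, dense sampling, brute-force loops).

# circularly roll a matrix so content moves by +dx columns, +dy rows
roll_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  img[ri, ci, drop = FALSE]
}

# shift image content by a fractional (+dx, +dy) via the Fourier phase ramp
fourier_shift <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  ky <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)]
  kx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)]
  phase <- exp(-2i * pi * (outer(ky * dy / nr, kx * dx / nc, `+`)))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (nr * nc)
}

# global displacement between two images by FFT cross-correlation with the
# correlation peak re-evaluated on an upsampled grid (default 1/100 px)
# around the integer peak; returns c(dx, dy)
oracle_shift <- function(ref, img, up = 100, halfwidth = 1) {
  nr <- nrow(ref); nc <- ncol(ref)
  F <- Conj(stats::fft(ref - mean(ref))) * stats::fft(img - mean(img))
  cc <- Re(stats::fft(F, inverse = TRUE)) / (nr * nc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dy0 <- pk[1] - 1; if (dy0 > nr / 2) dy0 <- dy0 - nr
  dx0 <- pk[2] - 1; if (dx0 > nc / 2) dx0 <- dx0 - nc
  ky <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)]
  kx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)]
  sy <- seq(dy0 - halfwidth, dy0 + halfwidth, by = 1 / up)
  sx <- seq(dx0 - halfwidth, dx0 + halfwidth, by = 1 / up)
  Ey <- exp(2i * pi * outer(sy, ky) / nr)
  Ex <- exp(2i * pi * outer(kx, sx) / nc)
  grid <- Re(Ey %*% F %*% Ex) / (nr * nc)
  pk2 <- which(grid == max(grid), arr.ind = TRUE)[1, ]
  c(dx = sx[pk2[2]], dy = sy[pk2[1]])
}

# analytic ground-truth displacement of a motion_spec arranged on the grid
# of a displacement_field, as u/v matrices
truth_on_grid <- function(spec, field, t) {
  pts <- cbind(rep(field$grid_x, each = length(field$grid_y)),
               rep(field$grid_y, times = length(field$grid_x)))
  uv <- analytic_displacement(spec, pts, t)
  list(u = matrix(uv[, 1], nrow = length(field$grid_y)),
       v = matrix(uv[, 2], nrow = length(field$grid_y)))
}

# RMS vector error between a field and matrices (over a cell mask)
field_rms <- function(field, u_true, v_true, mask = field$valid) {
  sqrt(mean((field$u[mask] - u_true[mask])^2 +
            (field$v[mask] - v_true[mask])^2))
}

# brute-force contraction time: dense resampling of a sampled trace is NOT
# wanted here -- for analytic signals we sample the *formula* densely
dense_t_contract <- function(fn, period, d_peak, sample_rate = 1e4) {
  tt <- seq(0, period, by = 1 / sample_rate)
  tt <- tt[tt < period]
  period * mean(fn(tt) > 0.1 * d_peak)
}
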