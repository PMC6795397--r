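test_that("piv parameter validation enforces the window contract", {
  expect_error(piv_params(window_size = 4), "window_size")
  expect_error(piv_params(window_size = 16, overlap = 16), "overlap")
  expect_error(piv_params(validation_threshold = 0), "validation_threshold")
  expect_silent(piv_params(window_size = 16, overlap = 0))
})

test_that("identity comparison yields exactly zero displacements", {
  tex <- small_texture()
  f <- piv_displacement(tex, tex, small_params())
  expect_true(any(f$valid))
  expect_true(all(f$u[f$valid] == 0))
  expect_true(all(f$v[f$valid] == 0))
})

test_that("integer circular shifts are recovered exactly away from the seam", {
  tex <- small_texture()
  shifted <- roll_image(tex, dx = 3, dy = 5)
  params <- piv_params(window_size = 16, overlap = 8, search_margin = 6)
  f <- piv_displacement(tex, shifted, params)
  # windows whose search region may touch wrapped content are excluded
  reach <- 16 + 6 + 5  # window + margin + shift
  clean <- outer(f$grid_y > reach & f$grid_y < 128 - reach,
                 f$grid_x > reach & f$grid_x < 128 - reach, `&`)
  sel <- clean & f$valid & !f$replaced
  expect_gt(sum(sel), 20)
  expect_true(all(f$u[sel] == 3))
  expect_true(all(f$v[sel] == 5))
})

test_that("subpixel shifts are recovered within 0.2 px RMS of the upsampled-correlation oracle", {
  tex <- small_texture()
  img <- fourier_shift(tex, 0.4, 0.7)
  orc <- oracle_shift(tex, img)
  expect_equal(unname(orc), c(0.4, 0.7), tolerance = 0.05)
  f <- piv_displacement(tex, img, small_params())
  sel <- f$valid & !f$replaced
  rms <- sqrt(mean((f$u[sel] - orc["dx"])^2 + (f$v[sel] - orc["dy"])^2))
  expect_lt(rms, 0.2)
})

test_that("per-window estimates agree with the oracle on random subpixel shifts", {
  set.seed(42)
  for (k in 1:10) {
    tex <- make_speckle_texture(96, 96, 700, 1.2, seed = 100 + k)
    d <- runif(2, -2, 2)
    img <- fourier_shift(tex, d[1], d[2])
    orc <- oracle_shift(tex, img)
    f <- piv_displacement(tex, img, small_params())
    sel <- f$valid & !f$replaced
    expect_gt(sum(sel), 10)
    rms <- sqrt(mean((f$u[sel] - orc["dx"])^2 + (f$v[sel] - orc["dy"])^2))
    expect_lt(rms, 0.1)
  }
})

test_that("translation equivariance: shifting both images leaves the field unchanged", {
  stack <- small_stack(noise = 0)
  a <- stack$frames[[1]]; b <- stack$frames[[8]]
  f0 <- piv_displacement(a, b, small_params())
  # shift both images by one grid cell (+8 px x, -8 px y): window (iy, ix)
  # of the shifted pair sees the pixels window (iy + 1, ix - 1) saw before,
  # so the fields must agree cell-for-cell after that offset
  f1 <- piv_displacement(roll_image(a, 8, -8), roll_image(b, 8, -8),
                         small_params())
  ny <- length(f0$grid_y); nx <- length(f0$grid_x)
  reach <- 16 + 4 + 8
  clean <- outer(f0$grid_y > reach & f0$grid_y < 128 - reach,
                 f0$grid_x > reach & f0$grid_x < 128 - reach, `&`)
  shifted0 <- f0$u[2:ny, 1:(nx - 1)]
  sel <- clean[1:(ny - 1), 2:nx] & f1$valid[1:(ny - 1), 2:nx] &
         f0$valid[2:ny, 1:(nx - 1)]
  expect_gt(sum(sel), 20)
  expect_equal(f1$u[1:(ny - 1), 2:nx][sel], shifted0[sel])
  expect_equal(f1$v[1:(ny - 1), 2:nx][sel], f0$v[2:ny, 1:(nx - 1)][sel])
})

test_that("antisymmetry: swapping reference and frame negates the field", {
  stack <- small_stack(noise = 0)
  a <- stack$frames[[1]]; b <- stack$frames[[9]]  # mid-contraction
  params <- piv_params(window_size = 32, overlap = 16, search_margin = 4)
  fab <- piv_displacement(a, b, params)
  fba <- piv_displacement(b, a, params)
  sel <- fab$valid & fba$valid & !fab$replaced & !fba$replaced
  expect_gt(sum(sel), 20)
  expect_lt(max(abs(fab$u[sel] + fba$u[sel])), 0.1)
  expect_lt(max(abs(fab$v[sel] + fba$v[sel])), 0.1)
})

test_that("flat images give invalid windows, and all-invalid pairs raise", {
  flat <- matrix(0.5, 96, 96)
  f <- piv_displacement(flat, flat, small_params())
  expect_false(any(f$valid))
  stack <- frame_stack(list(flat, flat, flat), frame_rate = 20)
  expect_error(consecutive_speed_trace(stack, small_params()),
               "frames 1 and 2")
})

test_that("images below the window + margin size are rejected", {
  small <- matrix(runif(20 * 20), 20, 20)
  expect_error(piv_displacement(small, small, small_params()), "too small")
  expect_error(piv_displacement(small, matrix(0, 21, 21), small_params()),
               "identical dimensions")
})

test_that("speed trace of a static video is zero with length n - 1", {
  tex <- small_texture()
  stack <- frame_stack(list(tex, tex, tex, tex), frame_rate = 20)
  sp <- consecutive_speed_trace(stack, small_params())
  expect_length(sp, 3)
  expect_true(all(sp == 0))
  expect_equal(select_reference_frame(stack, small_params()), 1L)
  two <- frame_stack(list(tex, tex), frame_rate = 20)
  expect_length(consecutive_speed_trace(two, small_params()), 1)
})

test_that("speed trace of a beating video is periodic with rest-phase minima", {
  sp <- consecutive_speed_trace(small_stack(noise = 0), small_params())
  expect_length(sp, 39)
  # one 1.0 s period = 20 frames
  expect_equal(sp[1:19], sp[21:39], tolerance = 0.02)
  # analytic inter-frame motion: mean |u*(t_{k+1}) - u*(t_k)| over the grid
  spec <- small_spec()
  f <- piv_displacement(small_texture(), small_texture(), small_params())
  pred <- vapply(seq_len(39), function(k) {
    a1 <- truth_on_grid(spec, f, (k - 1) / 20)
    a2 <- truth_on_grid(spec, f, k / 20)
    mean(sqrt((a2$u - a1$u)[f$valid]^2 + (a2$v - a1$v)[f$valid]^2))
  }, numeric(1))
  expect_gt(cor(sp, pred), 0.98)
  # minima fall in the rest phase (phase >= 0.7 or == 0)
  rest_frames <- which(amplitude_at(spec, (seq_len(40) - 1) / 20) < 1e-12)
  expect_true((which.min(sp[2:20]) + 1) %in% rest_frames)
})

test_that("the selected reference frame is diastolic", {
  stack <- small_stack(noise = 0.01)
  ref <- select_reference_frame(stack, small_params())
  spec <- small_spec()
  expect_equal(amplitude_at(spec, (ref - 1) / 20), 0)
})

test_that("displacement series tracks the analytic field against a fixed reference", {
  stack <- small_stack(noise = 0)
  spec <- small_spec()
  fields <- displacement_series(stack, ref_index = 1,
                                params = small_params())
  expect_length(fields, 40)
  # the reference frame maps to the identically zero field
  expect_true(all(fields[[1]]$u[fields[[1]]$valid] == 0))
  # every frame within 0.3 px RMS of the prescribed displacement
  for (k in c(5, 9, 12, 30)) {
    tru <- truth_on_grid(spec, fields[[k]], (k - 1) / 20)
    expect_lt(field_rms(fields[[k]], tru$u, tru$v), 0.3)
  }
  expect_error(displacement_series(stack, 99, small_params()), "ref_index")
})

test_that("a static stack yields all-zero displacement series", {
  tex <- small_texture()
  stack <- frame_stack(list(tex, tex, tex), frame_rate = 20)
  fields <- displacement_series(stack, 1, small_params())
  for (f in fields) expect_true(all(abs(f$u[f$valid]) == 0))
})

test_that("displacement fields export to long-format CSV", {
  dir <- withr::local_tempdir()
  stack <- small_stack(noise = 0)
  fields <- displacement_series(stack, 1, small_params())[1:2]
  p <- write_displacement_csv(fields, file.path(dir, "fields.csv"))
  tab <- read.csv(p)
  expect_named(tab, c("t", "grid_x", "grid_y", "u", "v", "valid"))
  expect_equal(nrow(tab), 2 * length(fields[[1]]$u))
})
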