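test_that("speckle texture is deterministic, bounded and nonuniform", {
  a <- make_speckle_texture(128, 128, 800, 1.0, seed = 7)
  b <- make_speckle_texture(128, 128, 800, 1.0, seed = 7)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_gt(var(as.vector(a)), 1e-4)
  expect_false(identical(a, make_speckle_texture(128, 128, 800, 1.0,
                                                 seed = 8)))
  expect_error(make_speckle_texture(128, 128, 0), "n_speckles")
  expect_error(make_speckle_texture(-5, 128, 10), "width")
})

test_that("affine displacement follows the closed form and validates input", {
  spec <- motion_spec(width = 128, height = 128, period = 1.0,
                      rest_fraction = 0, peak_divergence = 0.02,
                      n_frames = 40, center = c(64, 64))
  # diastolic rest: zero vector everywhere
  pts <- rbind(c(64, 64), c(10, 100), c(120, 3))
  expect_equal(analytic_displacement(spec, pts, 0),
               cbind(u = numeric(3), v = numeric(3)))
  # peak amplitude 0.02 at t = 0.5 -> s = 0.01, linear in (x - center)
  uv <- analytic_displacement(spec, rbind(c(64, 64), c(74, 64)), 0.5)
  expect_equal(unname(uv[1, ]), c(0, 0))
  expect_equal(unname(uv[2, ]), c(-0.1, 0))
  # divergence is -amplitude everywhere
  expect_equal(analytic_divergence(spec, pts, 0.5), rep(-0.02, 3))
  expect_error(analytic_displacement(spec, rbind(c(500, 10)), 0.5),
               "outside")
  expect_error(analytic_displacement(spec, rbind(c(64, 64)), 99), "within")
})

test_that("radial gaussian divergence matches finite differences", {
  spec <- small_spec(kind = "radial_gaussian", sigma = 30,
                     rest_fraction = 0)
  t <- 0.3
  h <- 1e-4
  probes <- rbind(c(64, 64), c(80, 64), c(40, 90), c(100, 100), c(64, 20))
  for (i in seq_len(nrow(probes))) {
    p <- probes[i, ]
    dudx <- (analytic_displacement(spec, rbind(p + c(h, 0)), t)[1, 1] -
             analytic_displacement(spec, rbind(p - c(h, 0)), t)[1, 1]) / (2 * h)
    dvdy <- (analytic_displacement(spec, rbind(p + c(0, h)), t)[1, 2] -
             analytic_displacement(spec, rbind(p - c(0, h)), t)[1, 2]) / (2 * h)
    expect_lt(abs(dudx + dvdy - analytic_divergence(spec, rbind(p), t)),
              1e-6)
  }
})

test_that("amplitude waveforms start at rest and respect the rest fraction", {
  for (wf in c("sin2_pulse", "triangle")) {
    spec <- small_spec(rest_fraction = 0.3,
                       waveform = if (wf == "sin2_pulse") "sin2_pulse"
                                  else "triangle")
    expect_equal(amplitude_at(spec, 0), 0)
    # rest phase occupies the last 30% of each cycle
    expect_equal(amplitude_at(spec, c(0.75, 0.9, 1.75)), rep(0, 3))
    expect_gt(amplitude_at(spec, 0.35), 0)
    expect_equal(max(amplitude_at(spec, seq(0, 1, by = 1e-4))),
                 spec$peak_divergence, tolerance = 1e-6)
  }
  expect_error(motion_spec(waveform = "custom", samples = c(0.5, 1, 0)),
               "start at 0")
  spec <- small_spec(waveform = "custom", samples = c(0, 1, 0, 0))
  expect_equal(amplitude_at(spec, 0.25), 1)  # linear interpolation
  expect_equal(amplitude_at(spec, 0.125), 0.5)
})

test_that("rendered video honors rest, periodicity and contraction motion", {
  tex <- small_texture()
  # zero amplitude: every frame is the texture, bit for bit
  still <- small_spec(peak_divergence = 0, n_frames = 5)
  stack <- render_beating_video(tex, still, noise_sigma = 0)
  for (f in stack$frames) expect_identical(f, tex)
  # one full period apart (1.0 s at 20 Hz): bit-identical frames
  stack <- small_stack(noise = 0)
  expect_identical(stack$frames[[1]], stack$frames[[21]])
  expect_identical(stack$frames[[3]], stack$frames[[23]])
  # frames at rest equal the texture exactly
  expect_identical(stack$frames[[1]], tex)
  # inter-frame intensity change is larger mid-contraction than at rest
  madiff <- function(k) mean(abs(stack$frames[[k + 1]] - stack$frames[[k]]))
  expect_gt(madiff(5), madiff(17))  # t ~ 0.2-0.25 s vs rest phase
  expect_error(render_beating_video(tex, small_spec(), noise_sigma = -1),
               "noise_sigma")
  big <- motion_spec(width = 256, height = 256, n_frames = 5)
  expect_error(render_beating_video(tex, big), "smaller")
})

test_that("rendering is deterministic per seed and noise has the set scale", {
  spec <- small_spec(n_frames = 6)
  a <- render_beating_video(small_texture(), spec, noise_sigma = 0.01,
                            seed = 5)
  b <- render_beating_video(small_texture(), spec, noise_sigma = 0.01,
                            seed = 5)
  expect_identical(a$frames, b$frames)
  clean <- render_beating_video(small_texture(), spec, noise_sigma = 0)
  resid <- a$frames[[1]] - clean$frames[[1]]
  expect_equal(sd(as.vector(resid)), 0.01, tolerance = 0.05)
})

test_that("ground-truth trace equals the spatially sampled |divergence|", {
  spec <- small_spec(rest_fraction = 0.2)
  ts <- c(0.1, 0.3, 0.62, 0.85)
  xs <- seq(5, 124, length.out = 40)
  g <- as.matrix(expand.grid(x = xs, y = xs))
  for (t in ts) {
    sampled <- mean(abs(analytic_divergence(spec, g, t)))
    expect_lt(abs(sampled - ground_truth_trace(spec, t)), 1e-6)
  }
  # radial field: linearity in amplitude makes the trace a scaled waveform
  rspec <- small_spec(kind = "radial_gaussian", sigma = 30)
  ts2 <- c(0.1, 0.3, 0.62)  # within the contraction pulse
  tr <- ground_truth_trace(rspec, ts2)
  expect_equal(tr / amplitude_at(rspec, ts2),
               rep(tr[1] / amplitude_at(rspec, ts2[1]), 3),
               tolerance = 1e-12)
})

test_that("dense-sampling ground-truth metrics match closed forms", {
  # sin^2 pulse with no rest: mean = peak/2, above-10% fraction known
  spec <- small_spec(rest_fraction = 0, period = 1.0)
  gt <- ground_truth_metrics(spec)
  expect_equal(gt$d_peak, 0.02, tolerance = 1e-6)
  expect_equal(gt$d_mean, 0.01, tolerance = 1e-4)
  expect_equal(gt$t_cycle, 1.0)
  frac <- 1 - 2 * asin(sqrt(0.1)) / pi  # sin^2 above 0.1 fraction
  expect_equal(gt$t_contract, frac, tolerance = 1e-3)
  # with a rest phase the contraction time scales by the pulse width
  spec2 <- small_spec(rest_fraction = 0.3, period = 1.1)
  gt2 <- ground_truth_metrics(spec2)
  expect_equal(gt2$t_contract, frac * 0.7 * 1.1, tolerance = 1e-3)
  expect_equal(gt2$d_mean, 0.02 * 0.7 / 2, tolerance = 1e-4)
})

test_that("cq table simulation is exact at sd 0 and consistent at large n", {
  tab <- simulate_cq_table(c(ctl = 9.46, hlhs = 7.17), sd = 0,
                           n_per_group = 4, seed = 1)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$cq[tab$group == "ctl"] == 9.46))
  expect_true(all(tab$cq[tab$group == "hlhs"] == 7.17))
  # downstream fold change from the exact group means
  fold <- fold_change_ddct(tab$cq[tab$group == "hlhs"],
                           tab$cq[tab$group == "ctl"])
  expect_equal(fold, 2^2.29)

  expect_identical(simulate_cq_table(c(a = 1), 0.5, 3, seed = 9),
                   simulate_cq_table(c(a = 1), 0.5, 3, seed = 9))
  big <- simulate_cq_table(c(a = 5, b = -2), sd = 0.3, n_per_group = 10000,
                           seed = 1)
  expect_lt(abs(mean(big$cq[big$group == "a"]) - 5), 0.02)
  expect_lt(abs(mean(big$cq[big$group == "b"]) + 2), 0.02)
  expect_error(simulate_cq_table(numeric(0), 0.1, 3), "nonempty")
  expect_error(simulate_cq_table(c(a = 1), -1, 3), "sd")
})

test_that("cq tables with a control assay carry matched rows per sample", {
  tab <- simulate_cq_table(c(ctl = 25, trt = 24), sd = 0, n_per_group = 3,
                           seed = 1, control_means = c(ctl = 20, trt = 20))
  expect_setequal(unique(tab$assay), c("target", "control"))
  d <- normalize_dct(tab)
  expect_equal(nrow(d), 6)
  expect_true(all(d$dct[d$group == "ctl"] == 5))
})

test_that("motion specs round-trip through YAML", {
  dir <- withr::local_tempdir()
  spec <- small_spec(kind = "radial_gaussian", sigma = 25,
                     rest_fraction = 0.25)
  write_motion_spec(spec, file.path(dir, "spec.yaml"))
  back <- read_motion_spec(file.path(dir, "spec.yaml"))
  expect_equal(back, spec)
})

test_that("synthetic datasets write video, truth and spec to disk", {
  dir <- withr::local_tempdir()
  spec <- small_spec(n_frames = 8)
  paths <- write_synthetic_dataset(spec, dir, noise_sigma = 0, seed = 3,
                                   n_speckles = 500)
  expect_true(all(file.exists(unlist(paths))))
  stack <- read_frame_stack(paths$video, frame_rate = spec$frame_rate)
  expect_equal(length(stack), 8)
  # 16-bit quantization only
  direct <- render_beating_video(make_speckle_texture(128, 128, 500,
                                                      seed = 4),
                                 spec, noise_sigma = 0)
  expect_lt(max(abs(stack$frames[[1]] - direct$frames[[1]])), 1e-4)
  truth <- read.csv(paths$truth_trace)
  expect_equal(truth$D_star, ground_truth_trace(spec), tolerance = 1e-12)
})
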