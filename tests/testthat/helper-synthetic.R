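# Shared small synthetic fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# 128 px, 1.0 s period, 2 s of video at 20 Hz -- small but PIV-resolvable
small_spec <- function(n_frames = 40, rest_fraction = 0.3,
                       peak_divergence = 0.02, period = 1.0,
                       kind = "affine_contraction", ...) {
  motion_spec(kind = kind, width = 128, height = 128, period = period,
              peak_divergence = peak_divergence,
              rest_fraction = rest_fraction, frame_rate = 20,
              n_frames = n_frames, ...)
}

small_params <- function() {
  piv_params(window_size = 16, overlap = 8, search_margin = 4)
}

small_texture <- function(seed = 2) {
  key <- sprintf("tex%d", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_speckle_texture(128, 128, 1500, 1.2, seed = seed)
  .fixtures[[key]]
}

small_stack <- function(noise = 0, seed = 1) {
  key <- sprintf("stack%g_%d", noise, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- render_beating_video(small_texture(), small_spec(),
                                             noise_sigma = noise,
                                             seed = seed)
  .fixtures[[key]]
}
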