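# cardiomotion

Video-based contractility quantification for beating cardiomyocyte
monolayers, plus the relative-quantification arithmetic (2^−ΔΔCt fold
changes, percent differences, unpaired t tests) that accompanies such
assays.

Cultured heart-muscle monolayers beat spontaneously, and their contractile
function can be read out without touching the cells: track the optical
speckle pattern of the culture across a time-lapse recording, estimate the
tissue displacement field, and measure how much the tissue area changes
each beat. `cardiomotion` implements that measurement chain for people
studying cardiomyocyte physiology and pharmacology (and for anyone who
needs a tested, ground-truth-validated PIV + divergence pipeline in R):

1. **PIV** — per-frame displacement fields `u(x, t)` relative to a
   diastolic reference frame, by windowed zero-mean normalized
   cross-correlation with subpixel (three-point Gaussian) peak refinement.
   The reference frame is selected automatically as the frame with minimal
   cell velocity.
2. **Divergence** — `∇·u = ∂u/∂x + ∂v/∂y` by central differences on the
   interrogation-window grid: a nondimensional measure of relative area
   change, negative under contraction.
3. **Contractility trace** — `D(t)`, the spatial average of `|∇·u|` per
   frame.
4. **Beat metrics** — peak contractility `D_peak = max D(t)`, mean
   contractility `D_mean`, beat period `T_cycle` (mean inter-peak
   interval), and contraction time `T_contract` (time per cycle with
   `D(t) > 0.1 D_peak`).

Because raw recordings of this kind are rarely shareable, the package
ships a synthetic generator (`motion_spec()`, `render_beating_video()`)
that warps a speckle texture by a prescribed contraction field with
analytically known displacement, divergence and beat metrics — every stage
of the pipeline is validated against closed-form ground truth.

## Worked example

Synthesize a 4 s recording of a beating monolayer (20 Hz, 128 px, beat
period 1.0 s, peak divergence 0.02, noise σ = 0.01) and analyze it:

```r
library(cardiomotion)

spec  <- motion_spec(width = 128, height = 128, period = 1.0, n_frames = 80)
tex   <- make_speckle_texture(128, 128, 1500, 1.2, seed = 2)
stack <- render_beating_video(tex, spec, noise_sigma = 0.01, seed = 1)

ref   <- select_reference_frame(stack)        # -> 16 (a diastolic frame)
trace <- contractility_trace(displacement_series(stack, ref))
trace
#> contractility_trace (absolute): 80 frames over 3.95 s, max D = 0.01901

compute_metrics(trace, detect_beats(trace))
#> beat_metrics: 4 beats
#>   D_peak = 0.01901, D_mean = 0.00669
#>   T_cycle = 1.000 s, T_contract = 0.550 s
```

The prescribed ground truth is `D_peak = 0.02`, `T_cycle = 1.0` s and
(dense-sampling oracle) `T_contract = 0.557` s: the pipeline recovers the
period exactly, the contraction time within half a frame, and the peak
divergence within 5% on this small frame (0.2% at the default 256 px
regime). `run_contractility()` wraps the same chain with CSV/JSON outputs
and a full parameter manifest; `run_group_comparison()` compares the
metrics of two treatment groups.

The expression arithmetic works on published group means directly:

```r
fold_from_mean_cq(9.46, 7.17)      # 4.890561  -> a ~4.9-fold increase
percent_difference(1.30, 1.52)     # 16.92308  -> a 16.9% larger diameter

unpaired_t_test(c(0.012, 0.014, 0.016), c(0.018, 0.019, 0.020))
#> group_comparison (pooled, 2-tailed)
#>   a: 0.014 +/- 0.00115 (n = 3)   b: 0.019 +/- 0.000577 (n = 3)
#>   difference 0.005 (+35.7%), t = -3.873, df = 4, p = 0.01795
```

A thin command-line front end with `simulate` / `analyze` / `compare` /
`qpcr` subcommands is installed at `inst/scripts/cardiomotion`.

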