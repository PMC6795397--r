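---
title: "Quantifying monolayer contractility from beating-cell videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying monolayer contractility from beating-cell videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cardiomotion)
```

## The measurement model

A confluent cardiomyocyte monolayer beats collectively: during systole the
tissue contracts toward local centers, during diastole it relaxes back.
Filmed at sufficient frame rate (20 Hz here), this motion can be measured
without segmenting single cells by tracking the optical speckle pattern of
the culture — membrane-stain puncta, organelles, phase-contrast granularity.

The pipeline proceeds in four stages.

**1. Displacement by particle image velocimetry.** Each frame is compared
against a single *diastolic reference frame*. The image is tiled into
interrogation windows (default 32 px, 50 % overlap); for every window the
displacement is the integer shift, within a search margin, that maximizes
the zero-mean normalized cross-correlation between the reference window and
the shifted window of the current frame, refined to subpixel precision by a
three-point Gaussian fit through the correlation peak. Normalized
correlation makes the estimate insensitive to slow illumination drift;
windows with no texture (zero variance) or without a full search margin are
marked invalid rather than guessed. A neighbor-median validation pass
replaces isolated outlier vectors (residual above 2 px against the median of
their 3×3 neighborhood) by that median; replaced vectors stay usable, since
an unusable hole would also poison the divergence stencil around it.

The reference frame is chosen automatically: PIV on consecutive frame pairs
yields a mean-speed trace, and the frame minimizing the centered two-sided
speed (mean of the speeds to its previous and next frames) is taken as the
quietest moment of diastole. One fixed reference serves the whole recording;
re-referencing per beat would make traces from different beats incomparable
whenever the resting configuration drifts. Ties resolve to the earliest
frame.

**2. Divergence.** For a displacement field $u(x, t)$ measured in pixels on
a grid with spacing in pixels, the divergence
$\nabla \cdot u = \partial u/\partial x + \partial v/\partial y$
is nondimensional and measures the relative change of area: negative under
contraction, positive during relaxation, zero for rigid motion. It is
evaluated by central differences on the window grid. Central differences
are exact for affine fields — the leading local behavior of a smoothly
contracting tissue at window scale — and cost one grid cell of border;
any cell whose four-point stencil touches an invalid window is itself
invalid.

**3. The contractility trace.** $D(t)$ is the spatial average of
$|\nabla \cdot u|$ over valid cells, one value per frame. The absolute
value is the package default (`convention = "absolute"`): reported
contractility values are positive magnitudes, and the absolute average is
robust to a field that contains both a contracting center and its stretched
surroundings, which would partially cancel in a signed average. The signed
variant (mean of $-\nabla \cdot u$, contraction positive) is retained
behind a flag for diagnostics; whether a given published analysis averaged
the signed or absolute divergence is generally not recoverable from figure
legends, so the choice is documented rather than hidden. $\sqrt{D(t)}$ is
exposed as a shortening trace — a linear rather than areal strain measure
— and is defined only for the absolute convention.

**4. Beat metrics.** From $D(t)$:

* $D_{peak} = \max D(t)$ — the global maximum over the recording, read
  literally; per-beat peak values are also reported so a per-beat-mean
  variant can be formed by the caller.
* $D_{mean}$ — the time average over the entire recording, rest phases
  included.
* $T_{cycle}$ — the mean interval between detected beat peaks; undefined
  (reported `NA`, not an error) with fewer than two beats.
* $T_{contract}$ — per cycle, the time with $D(t) > 0.1\, D_{peak}$
  (strict inequality), i.e. the integral of the contraction indicator
  $H(t)$, evaluated as a Riemann sum at the frame interval. Cycles span
  midpoint to midpoint between adjacent peaks, with the first and last
  cycles clipped to the recording; the threshold uses the global
  $D_{peak}$.

Beat detection itself finds local maxima with topographic prominence at
least 30 % of $\max D$ and pairwise separation of at least 0.4 s (the
taller peak wins a conflict). Both parameters are relative or far from the
physiological regime (beat periods ≥ 1 s), so amplitude rescaling of the
trace provably leaves all timing metrics unchanged.

```{r analytic-example}
tt <- seq(0, 10 - 0.05, by = 0.05)                 # 20 Hz, 10 s
tr <- as_contractility_trace(tt, 0.02 * sin(pi * tt)^2)
compute_metrics(tr, detect_beats(tr))
```

For this analytic trace the closed forms are $D_{peak} = 0.02$,
$D_{mean} = 0.01$, $T_{cycle} = 1$ s, and the above-threshold fraction of a
$\sin^2$ pulse is $1 - 2\arcsin(\sqrt{0.1})/\pi \approx 0.795$; the 20 Hz
Riemann sum gives 0.75 s, within half a frame per cycle edge of that value.

## The synthetic ground truth

Real recordings of beating monolayers are rarely redistributable, so the
package ships a generator whose output has *analytically known* answers at
every stage. A static speckle texture (Gaussian blobs with random position
and amplitude — guaranteed PIV-trackable contrast) is warped by a
prescribed displacement field:

* `affine_contraction`: $u^*(x,t) = -s(t)(x - c)$, divergence
  $-2s(t) = -a(t)$ everywhere, so the waveform amplitude *is* the absolute
  divergence;
* `radial_gaussian`: $u^*(x,t) = -s(t)(x-c)\,e^{-r^2/2\sigma^2}$ with the
  closed-form divergence $-s(t)(2 - r^2/\sigma^2)e^{-r^2/2\sigma^2}$, for
  a spatially localized contraction.

The amplitude waveform is a raised $\sin^2$ pulse occupying the first
$1 - \texttt{rest\_fraction}$ of each cycle — smooth, starting and ending
at zero, with a quiescent diastolic interval that gives the
reference-frame selector a genuine rest phase to find. Warping uses inverse
mapping (exact inversion for the affine field, a fixed-point iteration for
the radial one) with bilinear interpolation by default, because forward
splatting of texture pixels leaves holes. Zero-mean Gaussian intensity
noise is added per frame.

The default regime — 256×256 px, 20 Hz, 10 s, period 1.1 s, peak
divergence 0.02, noise σ = 0.01 — is scaled to sit inside the ranges
reported for embryonic cardiomyocyte monolayers ($D_{peak}$ around
0.014–0.019, beat periods around 1.1–1.2 s), so a recovery test on it
exercises the pipeline at realistic signal levels. Since period ×
frame rate is an integer here, frame phases are computed by integer
arithmetic and noise-free frames one period apart are bit-identical — a
deliberately strong determinism property that the tests assert literally.

What the generator does *not* emulate: phase-contrast optics (halos,
shading), cell-boundary structure, out-of-plane motion, photobleaching,
stage drift, or spatially heterogeneous beating (multiple pacemakers,
propagation waves). Passing the recovery tests therefore demonstrates the
correctness of the measurement chain on ideal kinematics, not robustness to
every artifact of live imaging; the validation and invalid-window
machinery is the main line of defense for the latter.

```{r recovery, eval = FALSE}
spec <- motion_spec()          # the default regime above
tex <- make_speckle_texture(256, 256, 2000, 1.5, seed = 2)
stack <- render_beating_video(tex, spec, noise_sigma = 0.01, seed = 1)
ref <- select_reference_frame(stack)
trace <- contractility_trace(displacement_series(stack, ref))
compute_metrics(trace, detect_beats(trace))
#> beat_metrics: 9 beats
#>   D_peak = 0.02004, D_mean = 0.007108
#>   T_cycle = 1.100 s, T_contract = 0.600 s
```

(Recovered $D_{peak}$ within 0.2 % of the prescribed 0.02; the dense-
sampling oracle for $T_{contract}$ is 0.612 s. Not run here — about 15 s.)

## Quantification arithmetic for companion measurements

Contractility experiments of this kind travel with qPCR and morphometry
comparisons, so the package includes their arithmetic:

* per-sample ΔCt against an endogenous control
  (`normalize_dct()`), and relative expression by
  $2^{-\Delta\Delta C_t}$ (`fold_change_ddct()`);
* `fold_from_mean_cq()` for the common situation where only per-group
  mean, already-normalized Cq values are published — such printed values
  can be negative or near zero, which raw Cq cannot be, so they are
  treated as group means on a normalized scale rather than re-normalized;
* percent differences of group means (`percent_difference()`), mean ±
  SEM summaries with the $n-1$ sample deviation (`group_summary()`), and
  unpaired $t$ tests (`unpaired_t_test()`) — pooled-variance Student by
  default with Welch behind a flag, since published methods sections
  typically say only "unpaired t test", and Student is what mainstream
  spreadsheet/Prism workflows produce; one-tailed p values are half the
  two-tailed value for the observed direction.

No multiple-testing correction is applied to these few planned
comparisons. qPCR efficiency correction and standard-curve quantification
are out of scope.

```{r expression}
fold_from_mean_cq(9.46, 7.17)        # ~4.9-fold up
percent_difference(0.014, 0.019)     # ~+36% peak contractility
unpaired_t_test(c(0.012, 0.014, 0.016), c(0.018, 0.019, 0.020))
```

## Numerical choices and degenerate inputs

* **Subpixel estimator.** Three-point Gaussian fit per axis; where a
  neighboring correlation value is non-positive (so its log is undefined)
  the parabolic fit is used instead; a peak on the search border is left
  at integer precision. When the correlation peak equals 1 to within
  1e-9 — a bit-identical match — refinement is skipped, so identical
  frames yield exactly zero displacement and pure integer shifts are
  returned exactly.
* **Tie-breaks.** Equal correlation maxima resolve to the first shift in
  scan order; equal reference-frame speeds resolve to the earliest frame;
  a beat-peak plateau reports its first sample.
* **Validation.** The median test runs on the pre-validation validity
  mask; replacements are computed from non-outlier neighbors; an outlier
  with no trustworthy neighbor keeps its measured value.
* **Flat windows** are invalid, not errors; a frame pair with *no* valid
  window raises an error naming the pair. An all-flat image therefore
  fails loudly, not silently.
* **Grid hygiene.** Divergence requires at least a 3×3 window grid and a
  uniform spacing; the contractility average errors on a frame with zero
  valid divergence cells rather than returning NaN.
* **Determinism.** Every stochastic step takes an explicit seed and
  restores the caller's RNG state; `run_contractility()` reruns
  bit-identically from the same configuration, and its manifest records
  every parameter needed to do so.

## Problem sizes used in the test suite

Unit and property tests run on 96–128 px textures with 16 px windows and
2 s recordings — small enough to iterate on, large enough for a 13×13
window grid. The end-to-end recovery checks use the full default regime
(256 px, 200 frames) over five seeds, asserting $D_{peak}$ within 15 % of
the prescribed 0.02, $T_{cycle}$ within 0.05 s of 1.1 s, and
$T_{contract}$ within 10 % of the dense-sampling oracle; observed errors
are far inside those bands (≈0.2 %, ≈0 s, ≈2 %).

## Known limitations

* The divergence is averaged over the field of view; spatially
  heterogeneous cultures (partial confluence, multiple beating domains)
  are summarized by a single trace that blends them.
* $T_{contract}$ at 20 Hz carries a quantization of up to one frame
  interval per cycle edge; the Riemann-sum convention slightly
  underestimates the dense-sampling value for pulse-shaped traces.
* The search margin bounds the largest measurable displacement (default
  6 px); strongly contracting fields need a larger margin or a larger
  window.
* Only single-channel grayscale input is supported; color stacks are
  averaged on read.
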