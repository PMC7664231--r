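---
title: "Camera-based sheep vitals: models, synthetic study conditions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based sheep vitals: models, synthetic study conditions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
measurement model, the two-stage machine-learning refinement, what the
synthetic scene generator does and does not emulate, and the numerical
decisions a maintainer would want spelled out. Code chunks are illustrative
and not evaluated at build time; everything quantitative here is computed by
the test suite or by `scripts/acceptance.R`.

## 1. Measurement model

Blood volume and respiratory perfusion change the light reflected by exposed
skin. On a sheep the usable window is the nose/mouth region (least wool); a
camera watching that region sees tiny periodic luminosity changes. The
package reduces a cropped, tracked video to two one-dimensional series, one
value per frame:

* **green channel mean** — cardiac pulse (classic rPPG choice, haemoglobin
  absorption peaks in green);
* **CIELAB a\* mean** — respiration, via the green–red opponent axis (skin
  reddening/cooling with each breath cycle).

"Luminosity of a channel" is defined as the plain spatial mean over the crop.
This is the only reading consistent with one value per frame, and matches
standard rPPG practice; no chrominance combinations (POS/CHROM) are used.

Each series is mean-centred and linearly detrended immediately at
extraction. Illumination drift is otherwise the largest spectral component
and would dominate the lower band edge (0.2 Hz). Frames flagged invalid by
tracking are filled by linear interpolation between valid neighbours —
zero-filling would inject broadband energy exactly where the rates live.

The sRGB → CIELAB conversion is the textbook path (IEC 61966-2-1 de-gamma,
XYZ under D65, CIE f-functions). The reference white is taken as the row sums
of the RGB→XYZ matrix so that neutral pixels give exactly a\* = 0; the
conversion agrees with `grDevices::convertColor` to < 0.2 in each
coordinate, which a unit test pins down.

## 2. Spectral core

The rate estimator is deliberately simple and fully deterministic:

1. **Zero-phase Butterworth band-pass.** An order-2 Butterworth prototype is
   mapped to a band-pass (4 poles) by the bilinear transform with frequency
   pre-warping (`signal::butter`), then applied forward and backward. The
   bidirectional pass squares the magnitude response: unity in-band, −6 dB at
   the cutoffs, and zero phase, so peaks are not displaced in time. Edge
   transients are controlled the way mainstream DSP toolboxes do it: odd
   reflection padding of 3 × (filter length − 1) samples plus steady-state
   initial conditions from the filter's companion matrix. A property test
   verifies the implementation against direct frequency-domain multiplication
   by |H(f)|² to 10⁻⁶ RMS away from the record edges (transients decay as
   max|pole|ᵏ, which for the test band means 24-sample margins on a 64-sample
   record).
2. **Spectrum.** Hann window, zero-padding to the next power of two ≥ 4n,
   one-sided magnitudes scaled so a unit-amplitude bin-centred sinusoid reads
   1.0. A one-minute record has a raw resolution of 1/60 Hz (1 BPM); the 4×
   zero-padding plus three-point parabolic interpolation around the argmax
   refines peaks well below 0.01 Hz, which the recovery suite checks.
3. **Band restriction.** The argmax is taken inside the requested band only.
   If it lands on a boundary bin the estimate is pinned there and flagged
   `edge_peak` — this happens legitimately, e.g. for true respiration just
   outside the wide band (see below). The spectrum is computed on the
   band-filtered series, mirroring the re-analysis semantics of the two-stage
   pipeline.

Bands (Hz): HR 0.83–3.00; RR-wide 0.33–3.1; RR-low 0.2–1.2; RR-medium
1.2–2.2; RR-high 2.2–3.2. Note the structural quirk: the union of the three
class bands (0.2–3.2) is wider than the single wide band. True rates in
0.2–0.33 or 3.1–3.2 Hz therefore *cannot* be measured by the wide-band pass —
one reason the band classifier exists. Frequencies exactly on a class
boundary belong to the lower band (half-open convention, matched by the
generator's labels).

## 3. Two-stage refinement

Sheep respiration runs from resting (~0.2 Hz) to heavy panting (> 3 Hz). In
a wide analysis band the spectral argmax is easily captured by slow chromatic
drift or other in-band disturbances, so the raw wide-band respiration
estimate is unreliable. The package follows a classify-then-refine design:

* **Model 1** — band classifier. Input: 8 parameters of the wide-band a\*
  analysis (mean, min, max, SD of the *first differences* of the detrended
  raw series; mean and SD of the filtered series; peak frequency and
  amplitude). Architecture: 10 tan-sigmoid hidden units, 3 softmax outputs.
  The first-difference statistics matter: differencing weights frequency f by
  2·sin(πf/fs), so they carry band information even when the spectral peak
  has been hijacked — that is what lets the classifier recover scenes whose
  wide-band frequency feature is wrong. ("Luminosity changes" is read as
  first differences; `compute_features(diff_changes = FALSE)` exposes the
  alternative reading of raw-series statistics.)
* **Re-analysis** — the a\* series is re-filtered and re-peaked inside the
  predicted class band, identical to calling the spectral core with that
  band.
* **Model 2** — vitals regression. Input: 8 cardiac-band parameters of the
  green series ⊕ 8 band-specific respiratory parameters (16 total; the count
  is a design choice — symmetric use of all engineered parameters). Two
  linear outputs predict HR (BPM) and RR (BrPM). Targets are standardized
  per output on the training rows and de-standardized at prediction.

Features are min–max normalized to [−1, 1] per column, with parameters
learned on the training rows only (tan-sigmoid input convention); test rows
may legitimately fall outside [−1, 1].

### Training

Both networks are trained by Bayesian-regularized Levenberg–Marquardt:
minimize F = β·E_D + α·E_W (E_D the output sum of squared errors, E_W the sum
of squared weights), LM damping μ scaled ×/÷10 on rejected/accepted steps,
and after each accepted step the evidence updates
γ = N_w − 2α·tr(H⁻¹), α ← γ/(2E_W), β ← (n_obs − γ)/(2E_D) with the
Gauss–Newton Hessian H = 2β·JᵀJ + 2αI. Observations are counted per scalar
(n_obs = samples × outputs: 188 for the training stage of the two-target
regression at the study size of 94 training samples). The classifier is
trained with squared error against one-hot targets on the linear output
activations, softmax applied at inference — the convention of the toolbox
trainers this mirrors. No validation split is used; the evidence updates
themselves suppress overfitting, and the no-overfitting signature
(training MSE ≤ testing MSE) is asserted by the acceptance suite.

Two engineering choices stabilize the trainer, both found necessary during
development and both documented here because the underlying literature is
silent about them:

* **Burn-in (default 25 epochs).** Starting the evidence updates at a nearly
  random network drives γ toward the Jacobian rank and α to enormous values,
  which collapses small over-parameterized problems (XOR is the canonical
  case) into the zero-weight solution. A short unregularized burn-in lets the
  data term organize first; the β update also uses the conventional floor
  max(n_obs − γ, 1).
* **Restarts (default 5).** The LM objective has init-dependent plateaus: on
  the same cohort some seeds reach 100% training accuracy and others stall
  at 97–98%. `fit_vitals_models()` trains a handful of seeded restarts per
  network and keeps the lowest final data error, making training performance
  reproducible across seeds rather than initialization luck.

## 4. ROI tracking

The tracker is a classical Kanade–Lucas–Tomasi chain: Shi–Tomasi corners
(minimum eigenvalue of the locally summed gradient structure tensor) seeded
inside a user-supplied box, pyramidal Lucas–Kanade flow (3 levels, 15 × 15
window, ≤ 30 iterations, ε = 0.01 px — the toolbox defaults, since the
original workflow does not state them), and a box update by the *median*
feature displacement, robust to partial occlusion. Headless operation
replaces any GUI labeler: the seed box comes from a CLI flag or a label file,
and label files (`frame,x,y,w,h[,valid]`, 0-based, optional
`# index_base: 1` header) round-trip losslessly.

A feature is dropped when any of three checks fails: frame-to-frame patch
residual; appearance monitoring against the feature's *original* template
(catches slow appearance capture); and a velocity gate — its flow must agree
with the track velocity within 0.75 px/frame. The velocity gate is essential
and non-obvious: a feature whose integration window merely *touches* a
static occluder (a cage bar) locks onto it with a *low* residual, reporting
near-zero flow while the animal moves on, and appearance checks cannot catch
it quickly. When fewer than 25% of the established features survive, the
frame is reported invalid: the published track carries the last valid box,
while internally the box coasts at its last velocity and freshly detected
features enter a probation state — they vote on the box only after their
motion has agreed with the track. This combination re-acquires the target to
within a couple of pixels after an occluder crossing. The cost is a
smooth-motion assumption (accelerations ≤ 0.75 px/frame²), acceptable at
30 fps for a feeding or resting animal.

Thermal stacks reuse the same machinery; the head ROI used for temperature is
large, so invalid frames simply inherit the last box.

## 5. Thermal statistics and THI

Per frame over the ROI: maximum, mode and population SD of the temperatures;
then mean, maximum, mode and SD of the per-frame maxima over valid frames.
The maximum is the physiologically meaningful statistic (eyes/nostrils are
the hottest visible spots and survive partial occlusion by colder bars —
a property the tests assert directly). The mode of continuous temperatures
needs binning: 0.1 °C bins centred on multiples of 0.1 °C (thermometer
display precision), ties to the lower bin, so a single-pixel ROI returns its
own value. SD is population (divide by N) — the per-frame pixel set is the
entire population of that frame, not a sample.

The sheep temperature–humidity index is THI = T − (0.31 − 0.31·RH)(T − 14.4),
T in °C, RH a *fraction* (values in (1, 100] are treated as percentages and
rescaled with a warning; the coefficient 0.31 − 0.31·RH must stay in
[0, 0.31], which fixes the unit). The bracket in the printed formula is
grouping, not a ceiling: a ceiling would make the index discontinuous in
both arguments, and the published sheep THI is the continuous Marai form.
Identities used as tests: THI = T at RH = 1; THI = 14.4 at T = 14.4 for all
RH; ∂THI/∂RH ≥ 0 for T > 14.4.

## 6. Evaluation statistics

Temperature and vitals agreement is summarized by through-origin regression:
slope b = Σxy/Σx², RMSE = √(Σ(y − bx)²/n), together with the ordinary Pearson
correlation (R and R² are reported jointly in the Pearson convention; the
uncentred through-origin R² is available behind a flag). Outliers are points
outside the two-sided t-based 95% *prediction* interval of the no-intercept
fit — confidence intervals on the mean would flag far more than ~5% of noisy
points and cannot be what a small printed outlier percentage refers to.
Classifier performance is reported per stage as accuracy/error/MSE (MSE
between softmax scores and one-hot truth) with a confusion matrix and
one-vs-rest ROC curves from a threshold sweep.

## 7. The synthetic study conditions

No animal recordings are distributed, so the generator *is* the study
population. It renders what matters to the measurement chain and nothing
more:

* smoothed random background texture (no photorealism), translating rigidly
  under a per-frame motion vector, with optional static vertical occluder
  bars;
* inside the (moving) ROI, the green channel carries
  base + amp_hr·sin(2π·hr·t) and the red channel
  base + amp_rr·sin(2π·rr·t) — red–green opponency makes the a\* channel
  respond to the red modulation;
* optionally a slow red-channel drift (sinusoid at 0.25–0.6 Hz), standing in
  for the chromatic trend that head motion and illumination geometry impose
  on real recordings;
* per-pixel Gaussian noise added in floating point *before* 8-bit
  quantization. This ordering is essential: sensor noise dithers sub-unit
  amplitudes through the quantizer, exactly as in a real camera, and without
  it a 0.3-DN cardiac amplitude would vanish entirely.

Recordings are one minute at 30 fps (the RGB stream's frame rate is not a
published camera constant; 30 fps is the configurable default and satisfies
Nyquist for 3.2 Hz with margin). Thermal scenes are a Gaussian hotspot of
specified peak trajectory over a uniform background at 9 Hz, the typical
longwave video rate.

A cohort (`generate_cohort()`) draws 134 scenes — the study size — balanced
over the three respiration bands, respiration uniform within each band
(0.2–3.2 Hz, i.e. 12–192 BrPM), heart rate uniform in 1.05–2.2 Hz
(63–132 BPM), labels 60 × frequency.

**Amplitude calibration.** The a\* axis responds ~1.4× more strongly to green
than to red at mid-gray, so the cardiac green modulation leaks into the
respiratory channel with that gain. The presets keep amp_hr well below
amp_rr (default 0.3 vs 2 DN) so the leak stays below 25% of the respiratory
amplitude; with equal amplitudes the leak would *dominate* a\* — a channel
property, not an estimator artifact.

**SNR presets.** These are calibration choices, set once from a scratch
experiment and frozen: real recordings publish no SNR figures. The `default`
preset (noise 2 DN, drift at 0.5–1.2 × amp_rr) is tuned so the pipeline
operates at the performance levels a realistic deployment reports: the drift
frequently captures the wide-band argmax (raw wide-band pooled correlation
≈ 0.5) while the band-classified re-analysis stays accurate (≈ 0.98), and
the band classifier lands in the mid-90s% overall. The `clean` preset
(noise 0.5 DN, no drift) represents favourable recordings and is where
training accuracy should saturate at 100%. What passing tests on these
cohorts shows is that the *measurement chain and models* behave correctly at
realistic signal levels; they cannot certify performance on real sheep,
where motion, fleece, illumination and physiology are all harder than this
texture model.

## 8. Numerical details and degenerate inputs

* Detrending: closed-form least-squares line removal; no windowed detrend.
* Filter edge handling: odd reflection, padlen = 3 × (ntaps − 1), steady-state
  initial conditions; signals shorter than 3 × ntaps are rejected.
* Peak interpolation is skipped (and flagged) when the argmax is a boundary
  bin; the interpolated offset is clamped to ±half a bin.
* Min–max normalization maps constant columns to 0 with a warning.
* γ is computed via the Cholesky solve of H; an eigenvalue fallback handles
  ill-conditioning. Singular damped systems raise μ and retry; non-finite
  losses abort with a diagnostic.
* The mode bin of an empty ROI, an all-invalid track, a textureless seed box,
  ragged thermal CSVs and decimal-comma exports are all explicit errors, not
  silent NA.
* Every stochastic routine (scene rendering, cohort draws, splits, weight
  inits) takes an explicit seed and restores the caller's RNG state;
  identical spec + seed is bit-identical output.

## 9. Problem sizes

The shipped test and acceptance runs use: two 134-scene cohorts of 60-second
40 × 40 px scenes with a 24 × 24 ROI (the ROI mean is what matters, so small
frames lose nothing); a 200-scene spectral-recovery ensemble at 28 × 28 px;
300-frame tracking scenes. These sizes keep a full run in the minutes range
on one CPU while preserving the study's sample sizes, record lengths and
frame rates.

## 10. Known limitations

* The generator's rigid translation + static bars do not model non-rigid
  head motion, specular highlights, fleece boundary effects or breathing
  motion of the ROI itself.
* The velocity-gated tracker assumes smooth motion; sudden direction
  reversals faster than 0.75 px/frame² break the gate.
* The a\*-channel respiration model is a single sinusoid; real panting is
  strongly non-sinusoidal (harmonics would appear in adjacent bands).
* Bands are fixed; animals whose true rates sit exactly on a class boundary
  are assigned to the lower band by convention, and rates outside 0.2–3.2 Hz
  are unmeasurable by construction.
* Model 2 is trained per cohort; no claim of transfer across cameras,
  illumination or breeds is made.
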