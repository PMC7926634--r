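---
title: "Contactless vital signs from thermal video: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless vital signs from thermal video: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermovitals)
```

## The measurement problem

A radiometric thermal camera mounted over an ICU bed delivers calibrated
temperature images (here nominally 382 × 288 px at 4 fps, 40 mK sensitivity)
without touching the patient. Three vital-sign surrogates can be read from
such video once per-frame bounding boxes for *patient*, *chest*, *head* and
*clinician* are available (from an object detector or manual annotation —
detection itself is outside this package's scope; boxes are consumed as
inputs):

* **Respiratory rate (RR)** — breathing displaces the chest surface by
  sub-pixel to few-pixel amounts. Dense optical flow on the chest crop,
  spatially averaged, yields a 1-D motion signal whose fundamental frequency
  is the breathing rate.
* **Body-surface temperature (BST) trend** — the maximum temperature in the
  head box proxies the warmest exposed skin. Because the absolute radiometric
  accuracy of low-cost cameras (±2 °C) is far worse than their sensitivity,
  only deviations from the first measurement point are reported, with an
  ambient estimate subtracted to cancel camera drift.
* **Clinician attendance** — the binary presence of a *clinician* box per
  frame, pooled into a time-of-day profile.

## Respiratory-rate pipeline

The chain is `chest_motion_signal()` → `bandpass()` → `autocorrelation()` →
`estimate_rr()`, composed by `extract_rr()` over an analysis window of
`window_frames` (default 960 frames = 240 s at 4 fps).

**Temporal filter.** Thermal video is noisy and low-contrast. Four
consecutive chest crops are buffered; the means of frames (t−2, t−1, t) and
(t−1, t, t+1) form the two flow inputs. For i.i.d. sensor noise this cuts
the variance by 3 while keeping the pair one frame apart, so the flow output
remains a per-frame-step displacement.

**Optical flow.** Farnebäck-style polynomial expansion: each neighbourhood
is fit by a Gaussian-weighted quadratic
\(f(\mathbf{x}) \approx \mathbf{x}^\top A \mathbf{x} + \mathbf{b}^\top
\mathbf{x} + c\), and the displacement field follows from the coefficient
changes between frames, refined iteratively over a coarse-to-fine pyramid
(implemented in C++; the separable-moment expansion is tested against a
per-pixel weighted least-squares oracle, the flow against analytic
translations and exhaustive block matching). Defaults: window 15 px,
σ = 4.5, 3 pyramid levels at scale 0.5, 3 iterations, 5-px averaging of the
normal equations. Two robustness choices deviate from the naive textbook
recipe, both forced by measurement:

* pyramid levels smaller than twice the expansion window are not built —
  such levels produce confident nonsense (the window covers the whole image,
  texture sits near Nyquist) that poisons finer levels;
* where the local normal-equation matrix is near-singular (flat patch,
  aperture problem) the prior displacement is kept instead of amplifying
  noise.

The two averaged crops are normalized **jointly** (one shared min-max map):
normalizing each input separately would alias global intensity changes into
apparent motion. Flow is averaged over all crop pixels, and the axis with
the larger variance is selected by default (`motion_axis = "auto"`), since
the projection of breathing motion onto image axes depends on camera pose.

**Bandpass.** A 2nd-order Butterworth bandpass (0.15–0.44 Hz, i.e.
9–26.4 bpm) is applied forward–backward (`filtfilt`), giving zero phase —
the pipeline is retrospective per window, and phase distortion would bias
the autocorrelation peak shape. "2nd order" refers to the analog prototype;
the digital filter has four poles (the scipy/Matlab convention). The design
was verified coefficient-for-coefficient against an independent reference
implementation; the designed −3 dB points land on 0.15/0.44 Hz exactly.

**Autocorrelation and peak picking.** The biased (divide-by-*n*) sample
autocorrelation, normalized to r(0) = 1, tapers long-lag noise peaks. Local
maxima with period inside the respiratory band are refined by three-point
parabolic interpolation — at 4 fps the integer lag grid alone quantizes RR
to ≈ 0.4–2 bpm steps — and the largest refined peak is selected, with one
guard: if another peak sits near **half** the chosen lag with at least 0.8
of its height, that peak wins. The guard exists because the coarse lag grid
can sample the 2T subharmonic closer to its continuum maximum than the
fundamental (true RR 25 bpm: T = 9.6 samples, and r[19] > r[10] despite the
taper), which would halve the reported rate.

**Validity.** A window is *invalid*, never a number, when: the picked peak is
below `peak_floor`; clinician boxes overlap the chest box in more than
`overlap_cap` (default 0.5) of samples (the crop then contains non-patient
motion); or more than `gap_cap` (default 10 %) of samples lost their chest
box for longer than `bridge_max` = 2 frames (shorter gaps reuse the last
box and are only flagged). The peak floor default is **0.5**, not lower:
narrow-band filtering makes pure sensor noise look quasi-periodic, and
measurement on noise-only scenes shows in-band ACF peaks of 0.22–0.32,
while genuine breathing at the lowest usable amplitude (0.25 px) scores
above 0.9. 0.5 is also the SNR = 1 point for a sinusoid in noise, so the
threshold has a physical reading.

## Temperature trend

Frames are grouped into measurement points of `aggregation_frames` frames
(default 240 ≈ 60 s; the literature is inconsistent between 240-frame
points and 960-frame windows, so the value is configuration, not code).
Per point: mean over frames of the per-frame head-box maximum, and the mean
of a 5 × 5 px upper-left-corner ROI as the ambient estimate. The corrected
deviation is

\[(T_\text{head}(t) - T_\text{amb}(t)) - (T_\text{head}(0) - T_\text{amb}(0)),\]

which cancels any additive drift common to head and corner *exactly* — that
is the model of camera/calibration drift, and it is what the synthetic
generator's `ambient_drift` emulates (a global additive term). Points
without any head detection are reported `missing`, never interpolated;
interpolation is presentation, not measurement. Absolute temperatures are
exported but should not be read clinically — only trends.

## Attendance profile

Per-frame binary presence is pooled across days into time-of-day bins
(default 60 min); the profile is 100 × mean(present) per bin, so 100 means
continuous presence at that hour. Empty bins are linearly interpolated
between their nearest occupied neighbours, circularly across midnight — the
choice of interpolation scheme is a declared assumption (the profile's
purpose is qualitative day/night structure).

## Detection metrics

IoU uses the continuous half-open box convention. Matching is greedy per
class in descending confidence (ties keep input order) at IoU ≥ 0.5;
average precision integrates the monotonized PR curve over all points (the
darknet evaluator's convention — which exact interpolation variant the
reference toolchain used is not documented, so all-point is recorded as an
assumption). Mean IoU is computed over matched true positives only; classes
absent from the ground truth are excluded from the mAP mean rather than
counted as zero. Coverage is the percentage of frames with at least one box
of a class — the accounting that decides which RR windows exist at all.

## The synthetic generator: what it does and does not establish

`generate_scene()` renders: background at room temperature, a warm torso
ellipse, a head ellipse whose plateau equals `core_temp` plus a linear
trend, a chest rectangle at ~33 °C carrying band-limited sinusoidal texture
(wavelengths 12–50 px) displaced vertically by
\(A \sin(2\pi f t)\) (optionally plus a 0.3 A first harmonic), transient
clinician ellipses, a global additive ambient/camera drift, and i.i.d.
Gaussian noise (default σ = 40 mK, the sensor class). Chest motion is
produced by evaluating the smooth analytic profile at shifted coordinates —
exact sub-pixel resampling, so sub-pixel flow against it is meaningful.
Ground truth (boxes, displacement, head and ambient series, presence) is
emitted alongside; rendering is bit-deterministic per seed
(Mersenne-Twister / inversion sampling, stated for cross-platform
reproducibility).

Defaults mirror the stated recording conditions: 382 × 288 px, 4 fps,
240 s windows, noise σ 0.04 K, breathing amplitude ~1 px, RR inside
9–26.4 bpm, clinician blobs at ~34 °C, head 36.8 °C, background 21 °C.
Tests render at reduced width/height (chest crop ≈ 50 × 30 px, inside the
range of real chest ROIs) purely for runtime; the temporal and noise
parameters are never reduced.

What a green synthetic test does **not** establish: performance on real
patients. The generator has no perspective change, no bedding occlusion, no
posture shifts, no seizures or ventilator artifacts, breathing is strictly
(quasi-)sinusoidal, and detector errors are modeled as independent drops
plus Gaussian corner jitter rather than the correlated failures real
detectors produce. The synthetic results validate the *algorithms against
their own measurement model*, nothing more.

## Numerical details worth knowing

* `normalize_frame()` is per frame (changing scene range changes per-frame
  contrast, which is the assumed behaviour of the downstream consumers); a
  constant frame maps to all zeros by convention.
* `crop()` snaps fractional boxes outward and clamps at frame borders with
  a `clipped` attribute instead of failing — border jitter is a detector
  property, not an error.
* The tiff16 dialect stores counts with a per-file linear map
  (°C = count·scale + offset, scale = range/65535), so the quantization
  step stays below the 40 mK sensitivity for any scene range below ~2.6 K
  per count step budget (a 20 K scene range gives 0.3 mK steps). Label
  files follow the darknet normalized `class x y w h` format with the fixed
  class order patient/chest/head/clinician.
* Bland–Altman limits are empirical 5th/95th percentiles, not ±1.96 SD;
  the grouped MAE summary is the **unweighted** mean across groups (the
  per-patient table convention), with the pooled per-pair MAE also
  returned.

## Known limitations

* No real-detector integration and no training: boxes come from files.
* The RR estimator reports one value per window; breath-to-breath
  variability is invisible by construction.
* `motion_axis = "auto"` assumes breathing dominates the selected axis; a
  patient translating slowly in-band along that axis would corrupt the
  estimate (real deployments gate on the patient box, out of scope here).
* The ambient correction model is additive; emissivity or distance changes
  (multiplicative effects) are not corrected.
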