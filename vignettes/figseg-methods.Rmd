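---
title: "figseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{figseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
its defaults are what they are. It covers the stimulus model, the
synthetic TMS-EEG generator, the preprocessing chain, the statistics, and
the numerical and design choices that were genuinely open.

## The experimental logic

Three random-dot stimuli share every low-level property — dot statistics,
motion energy per direction, border geometry, border flicker — and differ
only in how many regions segregate from the background: none
(*homogenous*), one (*frame*), or two (*stack*). Discriminating a figure
from a homogenous display requires only figure-border detection;
discriminating a stack from a frame additionally requires surface
segregation. Two difference waves therefore isolate the two stages:
figure − homogenous (stack and frame averaged first, then the homogenous
ERP subtracted) cancels local-motion and TMS-evoked activity and leaves
the border-detection correlate; stack − frame additionally cancels
border-related activity and leaves the surface-segregation correlate.
Double-pulse TMS over early visual cortex at early (96–119 ms),
intermediate (156–179 ms) or late (236–259 ms) windows probes when those
signals are causally needed.

## Stimulus model

The screen (1024 × 768 px by default) is tiled with one-pixel dots, each
black with probability 0.5. Two concentric squares centred at a fixed
offset from screen centre define the frame (153 px) and inner figure
(115 px) regions; everything else is background. A movie is four frames:
the pre-stimulus field, two motion refreshes, and the post-stimulus hold
(identical to the last motion frame — the continuing static display is
represented by that single held frame).

Per refresh, each region's dots translate `displacement` (1) pixels along
the region's direction, one of {45°, 135°, 225°, 315°}. Two choices were
open:

* **Border rule.** The design states only that dots never cross their
  region border. We delete dots that would cross and refill the vacated
  trailing-border pixels i.i.d. Bernoulli(0.5). This reproduces the
  "(dis)appearing dots" flicker, with an expected refill count that
  depends only on the shared geometry and displacement magnitude — hence
  exactly equal across stimulus kinds. Wrapping dots within regions would
  also satisfy the constraint but produces no flicker at all, which
  contradicts the design's explicit flicker-equality property.
* **Orthogonality.** Regions sharing a border always move in directions
  exactly 90° apart (never 180°), on every trial. For a stack this forces
  the inner region 180° from the background — acceptable because those
  two regions share no border. Enforcing orthogonality per trial (rather
  than only on average) is the stronger reading of "borders where motion
  was in orthogonal directions", and it keeps local motion contrast at
  borders identical between stack and frame on every single trial.

Direction assignment is uniform over the admissible set, so each
direction carries 1/4 of the motion energy in expectation for every kind;
`motion_energy_summary()` and `flicker_audit()` verify this by Monte
Carlo.

**Degrees versus pixels.** The nominal region sizes in degrees of visual
angle (17.99°, 3.23°, 2.42°, offsets 7.7°/10.64°, 0.64°/cm at 90 cm)
cannot all be realized simultaneously on the nominal monitor: the
vertical offset alone (10.64° ≈ 16.6 cm) exceeds the distance from screen
centre to the bottom edge of a 17-inch 1024 × 768 display. Region sizes
and offsets are therefore configured in pixels, with defaults that fit on
screen; the degree figures are carried as metadata and not enforced.

## Synthetic TMS-EEG generator

The generator exists so that every downstream stage can be tested against
known ground truth; it emulates the *statistical structure* the analysis
assumes, not the biophysics.

* **ERP components** are raised-cosine (Hann) bumps — smooth, compactly
  supported, two-parameter shapes. The *figural* component (−1.5 µV at
  the pool peak, 137–211 ms) is common to stack and frame; the *surface*
  component (+1.0 µV, 227–313 ms) is carried by stacks only. Spatial
  weights fall off as a Gaussian in great-circle angle (FWHM 70°) from
  the centroid of the peri-occipital pool, normalized so the pool mean
  weight is 1 — the stated amplitudes are pool amplitudes. Gains encode
  the simulated disruption: early TMS 0.2 for both components;
  intermediate TMS 1 (no disruption); late TMS 0.5 for the surface
  component only, mirroring the behavioral pattern in which late
  stimulation selectively degrades stack detection. No µV effect sizes
  exist to reproduce, so amplitudes are calibration choices, not
  reproductions.
* **Noise** is 1/f (exponent 1, 6 µV), white (2 µV), and 50 Hz line
  (1.5 µV) per channel, plus blinks (4/min, 150 µV on the vertical EOG,
  300 ms Hann kernel) projected to the scalp with a known frontally
  weighted topography, and a log-normal per-subject amplitude effect
  (sdlog 0.2). Channels are independent; no volume-conduction
  correlation structure, no realistic forward model, no drifts or
  electrode pops. Passing tests therefore certify the pipeline's
  arithmetic and its artifact handling, not its behaviour on every
  pathology of real recordings.
* **TMS artifacts** are biexponentially enveloped damped oscillations
  (peak 5 mV ≫ EEG scale, rise 0.8 ms, decay 6 ms, 180 Hz ring, clipped
  at ±5 mV), injected at both pulses of the 45 Hz pair. The real artifact
  is uncharacterized beyond its excision window; only its excision and
  interpolation are under test, so any large, fast transient serves.
* **Behavior** is drawn from per-condition 3 × 3 confusion matrices and
  log-normal RTs with additive per-condition shifts. Defaults encode the
  qualitative structure: frame detection selectively worst under early
  TMS; stack detection reduced under early and again under late TMS with
  late errors dominated by stacks called frames; a small, timing-
  unspecific dip for homogenous stimuli; figure→homogenous error rates
  independent of TMS. Sham mode keeps the no-TMS confusion matrix in all
  conditions but applies the RT shifts — slower, not less accurate.
* **ERP-level cohorts.** `simulate_erp_cohort()` skips the continuous
  recording and draws subject-level pooled condition ERPs directly:
  ground truth × subject gain + white residual noise. Its `noise_sd`
  (0.3 µV) is the residual sd of a subject condition mean and was
  calibrated once, by simulation, so that an 11-subject cohort recovers
  both injected windows in ≥90% of replicates — the design condition the
  generator is specified to meet. Power and false-positive studies use
  this generator; full-pipeline tests use the continuous one.

## Preprocessing chain

Stage order: excision/interpolation → mirror filtering → downsampling to
256 Hz → Cz re-referencing → ocular correction → artifact rejection →
surface Laplacian → epoching (−200…500 ms) → baseline (−100…0 ms) →
averaging → pooling.

* **Excision and interpolation.** Samples from −2 to 65 ms around each
  pulse-pair onset (67 ms, covering both pulses of the 23 ms pair) are
  replaced by a cubic-spline fit through 250 ms of context on each side;
  samples outside the window stay bit-identical. The fit is a *smoothing*
  spline rather than an interpolating one: a spline forced through every
  noisy context sample acquires noise-scale edge derivatives that blow up
  when continued across a 67 ms gap (hundreds of µV in practice), while
  the smoothing spline continues the low-frequency trend. It reproduces
  straight lines exactly and tracks a 5 Hz sinusoid across the gap with
  under 5% RMSE. Every interpolated sample is flagged, the flags survive
  downsampling and epoching, and flagged samples are excluded from all
  statistical tests.
* **Mirror filtering.** Filtering is applied to the signal and its
  time-mirrored extension (odd-reflection padding, 2 s per end) and
  combined forward–backward, giving exactly zero phase and strongly
  suppressed ringing at discontinuities such as excision boundaries —
  the tests verify a zero-lag cross-correlation peak and less post-step
  oscillation than single-pass causal filtering. The cascade is a
  2nd-order Butterworth high-pass at 0.5 Hz, a 4th-order Butterworth
  low-pass at 30 Hz, and a 2nd-order biquad notch at 50 Hz (2 Hz
  bandwidth). The high-pass order is 2 rather than 4 because at a
  normalized cutoff of ~1e-3 (0.5 Hz at 1048 Hz) higher-order Butterworth
  transfer functions are numerically fragile; the contract — zero-phase,
  passband-flat, ringing-free — is what is tested, since the original
  vendor kernel is unpublished.
* **Downsampling** to 256 Hz is cubic interpolation onto the new grid;
  the 30 Hz low-pass is far below the 128 Hz target Nyquist and serves as
  the anti-alias filter. A target sample inherits the interpolation flag
  if any source sample within half a target period was flagged.
* **Ocular correction** is regression-based: EOG propagation weights are
  estimated on blink-rich segments (vertical EOG beyond 4 robust SDs,
  dilated 150 ms; the whole recording if too few such samples) and the
  EOG channels are regressed out of every scalp channel. ICA-based
  correction is out of scope: its component-selection criteria are not
  reproducible from a written description. Degenerate inputs (absent or
  flat EOG) skip the stage with a warning.
* **Artifact rejection** drops trials with any scalp sample outside
  ±75 µV or any single-sample step above 50 µV. It runs on potential
  (µV) data *before* the Laplacian, because the thresholds are
  potentials, not Laplacian units — the one point where the printed
  stage order is ambiguous ("applied on all separate channels").
  Interpolated segments are exempt from the step criterion (their spline
  edges are not physiological steps). Rejecting everything raises a
  classed error carrying the report.
* **Surface Laplacian.** Spherical-spline current-source-density with
  stiffness m = 4, ridge regularization 1e−5 and a 50-term Legendre
  expansion — the common defaults of the spherical-spline literature.
  The transform is precomputed per montage; it maps constants to zero
  and is reference-free to numerical precision, and on the ℓ = 1 zonal
  harmonic it reproduces the −ℓ(ℓ+1) eigenrelation within 5% away from
  the electrode rim (edge electrodes extrapolate the spline and are not
  held to the analytic bound). The montage is an idealized unit-sphere
  10-10 layout (64 channels including mastoids and the full
  peri-occipital set).
* **Pooling** is the arithmetic mean over O1, O2, Oz, POz, PO3–PO8.

## Statistics

* **Sample-wise tests.** Two-tailed paired t-tests against zero at every
  non-flagged sample inside the a priori window (80–230 ms for
  figure − homogenous, 200–350 ms for stack − frame), with
  Benjamini–Hochberg step-up control at q = 0.05 applied across the
  tested samples of that window and contrast, separately per TMS
  condition. The family is the window — the narrowest defensible reading
  of "fixing the FDR" over a selected window; pooling conditions into one
  family would couple conditions with different masks (a window whose
  samples are all interpolated is reported as untestable, matching the
  intermediate-TMS figure window and the late-TMS surface window).
  Contiguous significant runs are reported as ms intervals;
  single-sample runs are flagged rather than suppressed. Zero-variance
  samples are reported as non-significant with a warning instead of ±∞.
* **Cumulative statistic.** Per subject and condition, the stack − frame
  pooled difference summed over 227–313 ms (units: signal × samples),
  compared between conditions by two-tailed paired t-tests; a
  correct-only variant recomputes the ERPs from correct trials. The late
  condition is excluded by default since its excision window overlaps
  the cumulation window.
* **RM-ANOVA.** The two-way within-subject decomposition is computed
  from scratch (each effect tested against its own effect-by-subject
  interaction); `aov()` error strata serve as an independent oracle in
  the tests, never as the implementation. Degrees of freedom are
  uncorrected by default — the design's reported dfs, (6, 60) at n = 11,
  are uncorrected — with Greenhouse–Geisser epsilon available via
  `gg = TRUE`. All-equal inputs return F = 0 rather than 0/0.
* **Behavioral filters.** RTs below 100 ms or above 1500 ms are removed
  (bounds themselves retained: "less than 100" is exclusive); subjects
  must *exceed* 67% overall accuracy, so exactly 67.0% is excluded.
  Accuracy is evaluated on the RT-filtered trials.
* **Directionality.** Pairwise behavioral comparisons are two-tailed by
  default here; the error-type comparisons are two-tailed with BH
  correction across all comparisons. One-tailed variants for predicted
  decrements can be obtained from the reported t and df.

## Problem sizes

Profiles bundle the design constants with a simulation scale:
`reference` is the full design (11 subjects, 25 × 96 trials at 1048 Hz),
provided as the canonical parameterization; `desk` (11 × 48 trials) and
`tiny` (3 × 24 trials) are the sizes the test-suite and fixtures use, and
at which a complete simulate → preprocess → stats cycle runs in minutes
on one CPU. Power and false-positive properties are established on
100–200 seeded replicates of 11-subject ERP-level cohorts; balance audits
use 1000 stimuli per kind on a reduced 96 × 64 px screen (the audited
properties are resolution-independent).

## Known limitations

* Channels' background noise is independent across electrodes; spatial
  statistics of the Laplacian on *noise* are therefore not realistic,
  only its response to the injected signal topographies.
* The excision spline models no TMS-evoked potential; in real data the
  interpolated segment can hide genuine evoked activity — the reason the
  analysis excludes interpolated samples from testing rather than
  trusting them.
* BrainVision I/O covers the multiplexed IEEE-float variant the package
  writes; vendor files with other binary layouts are rejected, not
  coerced. HDF5 export is not provided.
* No cluster-based permutation statistics, mixed-effects models, source
  localization or real-time presentation; sham physics is reduced to
  "RT shift, no accuracy change".
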