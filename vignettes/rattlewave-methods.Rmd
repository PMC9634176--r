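---
title: "From wrist accelerometry to bimanual coordination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wrist accelerometry to bimanual coordination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rattlewave quantifies how infants shake a rattle — how often, at what rate,
and how tightly the two arms coordinate — from wrist-worn tri-axial
accelerometers and a video coder's annotations. This vignette explains the
models and procedures, the parameters that matter, the synthetic-data
generator used for validation, and the design choices made where the
problem left the design genuinely open.

## The pipeline

A visit is processed in five stages:

1. **Pre-processing.** Missing samples in each axis are filled by cubic
   spline interpolation; the three axes are collapsed to the normalized
   acceleration `Acc(t) = sqrt(ax^2 + ay^2 + az^2)`; a third-order median
   filter removes one-point outliers. The order is fixed
   (interpolate, then norm, then smooth): interpolation operates on what
   the sensor actually measured, and the median filter should see the
   final one-dimensional signal.
2. **Synchronisation.** Sensor and video clocks are aligned on the
   mother's claps. Within a user-supplied clap window, samples more than
   one standard deviation above the window mean are binarized to 1,
   supra-threshold runs separated by 50 ms or less are merged, and the
   resulting sensor clap raster is compared with the rasterized video clap
   tier by a diagonal cross-recurrence profile: the recurrence rate as a
   function of integer-sample lag, over a ±6 s search (±15 s fallback).
   The profile's argmax is the video-minus-sensor lag; annotation times
   minus that lag are on the sensor clock.
3. **Movement events.** Within each aligned rattling episode, the same
   binarization (mean + 1 SD, computed per episode) and 50 ms merge rule
   yield discrete rattling movements; left- and right-arm supra-threshold
   intervals are combined by union, so a bimanual shake counts once.
   Rattling frequency is movements divided by total annotated rattling
   time; visits above 2.5 Hz are flagged as outliers and excluded.
4. **Coherence.** The rattling episodes of both arms are joined into two
   concatenated series and compared by Morlet wavelet coherence; the
   matrix is averaged over 0.5–2.5 Hz (the observed range of rattling
   frequencies) and all times. A shuffled-surrogate null (1000 independent
   permutations of both series) calibrates that band mean, and a paired
   t-test across visits compares observed values with their null means.
5. **Longitudinal summaries.** Per-visit metrics enter a long table and
   are analysed with generalized estimating equations (age and condition
   as repeated measures, exchangeable working correlation, robust Wald
   tests, Bonferroni-adjusted pairwise contrasts). Inter-rater agreement
   of the annotations is quantified frame-wise by Cohen's kappa.

## Wavelet coherence

The coherence of arms `x` and `y` is

    WC(a, b) = |S(Cx*(a,b) Cy(a,b))|^2 / ( S(|Cx(a,b)|^2) · S(|Cy(a,b)|^2) )

where `Cx`, `Cy` are continuous wavelet transforms at scale `a` and time
`b`, `*` is complex conjugation, and `S` is a smoothing operator in time
and scale. Values lie in [0, 1]: 1 means a consistent local phase
relation, 0 means none. Without `S` the ratio is identically 1 for any
inputs — the smoothing is what turns the expression into a statistic —
and the package exposes `smoothing = FALSE` purely as a negative control
that the test suite asserts.

Implementation choices, all configurable:

* **Mother wavelet**: analytic Morlet, centre frequency `omega0 = 6`, the
  standard compromise between time and frequency resolution. The
  transform runs in the Fourier domain over a dyadic grid of 12 voices
  per octave spanning 0.25–5 Hz, a margin around the analysis band.
* **Smoothing operator**: a Gaussian in time with SD equal to the scale,
  then a boxcar across scales of about 0.6 octave — the kernel family
  popularised by the geophysical wavelet-coherence literature. Spectra
  are divided by scale before smoothing. Because every weight is
  non-negative, the Cauchy–Schwarz inequality bounds the result in [0, 1]
  up to floating-point error; overshoot beyond 1e-6 raises an error
  rather than being clipped silently, since it would indicate a broken
  smoother.
* **Cone of influence**: recorded per the e-folding convention and drawn
  by the plot method, but `band_average()` includes all time columns by
  default (the band mean is defined over the full joined series);
  `coi_exclude = TRUE` gives the conservative variant.
* **Episode joins**: coherence is computed on the concatenated episode
  series, accepting the artifacts at the joins; movement events, by
  contrast, are never merged across joins.
* **Numerical validity**: for nearly noiseless narrowband inputs the
  smoothed auto-power can fall many orders of magnitude below the
  spectrum peak; such cells are dominated by FFT roundoff and are
  returned as `NA` (the cutoff is nine decades below the peak) rather
  than as garbage ratios. Broadband data never trigger the mask.
* **Surrogates**: full independent permutation of both series per
  iteration — the strongest null, destroying all autocorrelation — with
  the observed statistic and every null draw computed by the identical
  restricted-band kernel (compiled, since the null costs thousands of
  coherence evaluations per visit).

## Synchronisation details

The paper-and-pencil definition of the recurrence profile leaves the
normalization open. rattlewave divides the match count at each lag by the
smaller *total* number of active samples, a lag-constant denominator: a
perfect alignment scores 1 and profiles are comparable across lags.
(Normalizing inside each overlap was tried and rejected: a lag whose
overlap strands a single clap that happens to match scores a perfect
rate, and the estimator locks onto such false peaks.) Ties are broken
toward the smallest |lag|, negative first. Binary series make the
recurrence radius irrelevant: a match is simply two co-occurring ones.

The search widens from 6 s to 15 s automatically when fewer than half of
the claps match at the best 6 s lag (`widen_floor = 0.5`); a final peak
rate below 0.1 flags the estimate as low-confidence, replacing the
study's interactive visual check with a deterministic criterion plus the
static QC plot `plot_alignment()`.

Thresholds use the population SD, a fixed convention chosen for
bit-reproducibility; at window lengths of hundreds of samples the
difference from the sample SD is negligible.

## The synthetic dyad-session generator

No raw infant recordings are publicly deposited, so validation rests on
`generate_session()`, which emulates the recording setup: two 60 Hz
tri-axial wrist sensors over ~5 minutes, additive white Gaussian noise
per axis plus a constant gravity offset on one axis, sharp half-sine clap
transients near the session start, annotated rattling episodes with
maternal-rhythm condition labels, a known video-minus-sensor lag up to
±15 s, and optional random sample dropout to exercise the interpolation.

**Movement packets.** A rattling movement is simulated as a Tukey-windowed
(raised-cosine-tapered, flat-topped — real shakes start abruptly, and a
slow-rising envelope lets sensor noise chatter across the detection
threshold) *quadrature* (circular) oscillation on the two
gravity-orthogonal axes — a rotational wrist shake of two carrier cycles
at the episode's burst frequency. The quadrature pair makes the
acceleration magnitude a single smooth bump, `sqrt(1 + A^2 env(t)^2)`,
so one packet produces exactly one supra-threshold run and ground-truth
movement counts are well defined. (A plain windowed sinusoid was tried
first and rejected: its magnitude crosses the mean + 1 SD threshold once
per positive half-cycle, with inter-lobe gaps far beyond the 50 ms merge,
so one packet always counted as 2–3 movements.) The movement *rate* —
packets per second, around 0.5–1.3 Hz under the study-like layout — is
what lands in the 0.5–2.5 Hz analysis band, mirroring the real task,
where the reported rattling frequencies are movement rates.

**Coupling.** `coupling = 1` makes the right arm repeat the left arm's
packet times and carrier phases exactly; `coupling = 0` draws the right
arm's packet layout independently (same count, min-separation respected,
stick-breaking placement) and scrambles its carrier phases with circular
SD `(1 - coupling) * pi`; intermediate values interpolate the layouts.
Phase jitter alone is not enough: perfectly aligned envelopes are
themselves a strong bimanual coupling.

**Movement density.** `study_session_config()` fills episodes to 60% of
the maximal packet packing. Infants pause between shake bouts, and the
density matters statistically: at full packing both arms' movement trains
become near-periodic at the same rate, which is intrinsic coupling that
no independent layout can remove — uncoupled sessions would then sit
above their own permutation null. At 60% density the uncoupled condition
is genuinely null-like while the coupled condition stays far above it.

**Counting semantics.** Ground truth records per-arm packet counts. With
phase-locked arms the left/right supra-threshold intervals coincide and
the union count equals the per-arm count exactly; with uncoupled arms the
union legitimately exceeds it (the arms move at distinct moments), so
count-recovery checks use the phase-locked default.

**What the generator does not emulate:** orientation dynamics and
gravity rotation during real arm movement, sensor drift and quantization,
autocorrelated (pink) noise, variable infant effort across a session, or
mother-side movement. Passing tests therefore demonstrate that the
algorithms recover known structure from magnitude-level signals with
realistic noise — not that the pipeline is robust to every artifact of
real wearable data.

**Defaults.** Noise SD 0.05 and packet amplitude 0.8 (units of gravity;
all detection thresholds are relative, so units never enter), clap
amplitude 2, four claps in a 2–20 s window, five-minute sessions. The
sensors' true amplitude statistics are not published, so these are
order-of-magnitude choices exposed in `session_config()`.

## Statistical stage

The repeated-measures analysis is a Liang–Zeger GEE written in the
package (no GEE fitter is among the package's dependencies): families
gaussian/identity (durations, frequencies, coherence) and poisson/log
(counts); working correlation exchangeable by default, independence and
AR(1) as alternatives. Factors are tested with robust sandwich-covariance
Wald chi-square statistics; because the covariance is estimated from
finitely many subjects, p-values use the `F(df, K - p)` reference rather
than the asymptotic chi-square, which simulation shows is
anti-conservative at realistic cohort sizes (about 10% rejections at
nominal 5% with 30 subjects). Pairwise level contrasts use estimated
marginal means with Bonferroni adjustment. The test suite cross-checks
the independence case against a cluster-robust GLM covariance and the
two-timepoint case against a paired t-test.

Cohen's kappa is computed frame-wise at the video rate (25 fps default),
mirroring overlap-based agreement computation on annotation tiers. Note
that with long episodes the effective number of independent frames is the
number of episodes, not the number of frames: chance kappa concentrates
near zero only over recordings with many short episodes.

## Problem sizes used in validation

The packaged checks run at desk scale, chosen so the full suite completes
in minutes while keeping every statistic meaningful: one 300 s session
for the self-coherence identity; 200 pairs of 60 s noise sessions for the
[0, 1] bounds; 60 sessions of 60 s for lag recovery across ±15 s;
20 full 300 s visits of 15 episodes (~25–30 movements, as in the cohort's
later timepoints) for noisy movement-count recovery, where a ±10% bound
is meaningful; 20 sessions of 90 s (six episodes each) per coupling
level, with 1000-draw surrogate nulls, for the coupled/uncoupled
discrimination; and 200 simulated cohorts of 150 subjects for the GEE
type-I calibration.

## Known limitations

* Band means depend on the smoothing kernel; other implementations with
  different kernels will produce different absolute levels, so only
  analytic properties (self-coherence, bounds, null calibration), not
  published descriptive values, are reproducible targets.
* The lag search assumes claps are the dominant events inside the clap
  window; a window containing vigorous non-clap movement can defeat it
  (the low-confidence flag and QC plot are the guard).
* The GEE fitter targets the designs used here (a few hundred clusters,
  small factorial designs); it implements no small-sample covariance
  corrections.
* Annotation parsing supports the tab-delimited coder export, not the
  native XML of the annotation tool.
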