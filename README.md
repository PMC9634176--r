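# rattlewave

Quantifying infant rattle-shaking — movement counts, rattling frequency,
and bimanual coordination — from wrist-worn tri-axial accelerometers and
video-coded behavioural annotations.

In longitudinal parent–infant play studies, infants wear an inertial
sensor on each wrist while shaking a rattle, sometimes alone and sometimes
while the mother provides an auditory rhythm. A video coder marks the
onset and offset of every rattling episode (and of the mother's claps,
recorded for clock synchronisation). The scientific questions are
developmental: how many rattling movements does the infant make, at what
rate, and how tightly do the two arms coordinate — and how do these change
with age and with the social condition? rattlewave is a tested, reusable
implementation of that analysis pipeline, for researchers working with
wearable movement data and behavioural annotations.

## What it computes

* **Magnitude pre-processing** — cubic-spline interpolation of missing
  samples, the normalized acceleration
  `Acc(t) = sqrt(ax(t)² + ay(t)² + az(t)²)`, and a third-order median
  filter.
* **Sensor–video synchronisation** — claps are detected in the sensor
  magnitude as samples above the clap-window mean + 1 SD (runs ≤ 50 ms
  apart merged) and aligned with the video clap tier by a diagonal
  cross-recurrence profile over ±6 s (±15 s fallback); its peak is the
  video-minus-sensor lag.
* **Movement events** — the same mean + 1 SD + 50 ms-merge detector
  applied inside each aligned rattling episode (both arms combined by
  union) gives discrete rattling movements; rattling frequency is
  movements per second of annotated rattling time, with visits above
  2.5 Hz flagged as outliers.
* **Wavelet coherence** — between the two arms' joined episode series,

      WC = |S(Cx* · Cy)|² / ( S(|Cx|²) · S(|Cy|²) ),

  with `Cx, Cy` analytic Morlet continuous wavelet transforms and `S` a
  smoothing operator (Gaussian in time with SD equal to the scale, ~0.6
  octave boxcar across scales), averaged over the 0.5–2.5 Hz rattling
  band, plus a 1000-draw shuffled-surrogate null and a group-level paired
  t-test against it.
* **Longitudinal statistics** — generalized estimating equations (age ×
  condition repeated measures, exchangeable working correlation, robust
  Wald tests, Bonferroni pairwise contrasts) and frame-level Cohen's κ
  for inter-rater agreement.
* **A synthetic dyad-session generator** — sessions with known ground
  truth (movement counts and times, burst frequency, left–right coupling,
  clap times, sensor–video lag, condition labels), so every stage is
  testable without access to raw infant data.

File formats are plain text: sensor CSV (`time_s,ax,ay,az`), tab-delimited
annotation exports (`tier  onset_s  offset_s  label`, the coder-tool
export dialect — native XML is not parsed), and a per-visit summary CSV.

## Worked example

A full synthetic visit, processed end to end:

```r
library(rattlewave)

cfg <- study_session_config(seed = 42, true_lag_s = 3.2)  # 300 s @ 60 Hz
ses <- generate_session(cfg)

m_left  <- preprocess_sensor(ses$left)
m_right <- preprocess_sensor(ses$right)

# clap-based alignment of the video annotations onto the sensor clock
sy <- sync_session(m_left, ses$video_track, cfg$clap_window)
sy$lag
#> <lag_estimate> lag 3.2000 s (window 6 s, peak rate 1.000)

jl <- segment_episodes(m_left,  sy$aligned)
jr <- segment_episodes(m_right, sy$aligned)
cm <- count_movements(jl, jr)
vm <- visit_metrics(jl, cm, visit_id = "demo_T3")
wc <- wavelet_coherence(jl$acc, jr$acc, fs = 60)
vm$wavelet_coherence <- wc$band_mean
vm
#>   visit_id n_episodes mean_episode_dur_s n_movements rattling_freq_hz
#> 1  demo_T3          8           4.040242          14        0.4331424
#>   wavelet_coherence excluded
#> 1         0.8904581    FALSE

surrogate_null(jl$acc, jr$acc, n_iter = 1000, seed = 7, fs = 60)
#> <surrogate_null> observed 0.890 vs null 0.356 [0.301, 0.419] (1000 shuffles, p = 0.0010)
```

Reading the output: the estimated lag recovers the planted 3.2 s clock
offset exactly (every clap matched, peak rate 1). The visit has 8
annotated episodes averaging 4.0 s; 14 discrete rattling movements were
detected — the generator planted exactly 14 — giving a rattling frequency
of 0.43 Hz, below the 2.5 Hz outlier threshold. The band-averaged wavelet
coherence of 0.89 reflects the phase-locked arms of this session
(`coupling = 1`), and lies far above the shuffled-surrogate null
(mean 0.36, central 95% range 0.30–0.42), so the coordination is not a
chance property of the amplitude distribution. `write_visit_summary()`
stores such rows per visit × condition; `fit_repeated_effects()` analyses
the resulting longitudinal table.

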