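---
title: "Measuring retinal vein pulsation timing from synchronized fundus video and ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vein pulsation timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinpulse)
library(dplyr)
```

## The measurement problem

The central retinal vein pulsates with the cardiac cycle: once per beat it
briefly collapses at the optic nerve head, driven by the pressure gradient
across the lamina cribrosa. The *time to vein collapse* — the interval from
the ECG R-wave to the collapse event, written `T_vc`, in milliseconds or as
a percentage of the cardiac cycle — is a candidate marker for studies of
intraocular and cerebrospinal fluid pressure. `veinpulse` implements a
semi-automatic measurement chain for `T_vc` from a fundus video recorded by
a video-ophthalmoscope at 25 fps that is frame-synchronized, through a
hardware trigger, with biosignals (ECG + the trigger itself) sampled at
1000 Hz.

Because clinical recordings of this kind are not publicly distributable,
the package ships a synthetic-data module that emulates the whole
acquisition chain with known ground truth: every processing stage can be
validated by parameter recovery, and all tests run without hardware or
external data.

## The processing model

The chain mirrors the acquisition system's geometry: one video frame
starts at every rising trigger edge, so at 25 fps and 1000 Hz each frame
spans exactly 40 biosignal samples and frame timestamps are exact sample
indices.

1. **R-wave detection.** The ECG is median filtered (size 10 samples),
   Gaussian smoothed (sigma 12 samples), and baseline-corrected by
   subtracting a Gaussian low-pass (sigma 200 samples); filter sizes are
   defined at 1000 Hz and scale proportionally at other rates. Local
   maxima are then accepted with all-adaptive parameters computed on the
   filtered signal: height threshold `max/4`, topographic prominence
   `(max - min)/2`, and a minimum separation of 0.545 s (a 110 bpm
   ceiling). Adaptive thresholds make detection exactly invariant to any
   positive rescaling of the ECG.
2. **Trigger edges.** The same peak picker runs on the first-order
   difference of the trigger channel, with a threshold of half the square
   wave magnitude, a minimum separation of 0.6 frame periods, and no
   smoothing or prominence criterion. The signal minimum is prepended
   before differencing so a recording that starts in the high state still
   counts its first edge.
3. **Frame alignment.** Translation-only registration of every frame to
   the first by phase correlation: the frames are Hann-windowed, the
   whitened cross-power spectrum gives the integer displacement, and a
   parabolic fit on the plain cross-correlation around that peak gives
   the sub-pixel part. (The fully whitened peak is a delta function, so
   its neighbours carry only noise — sub-pixel refinement must use the
   broad unwhitened lobe.) Whitening is regularized so that out-of-band,
   noise-only spectral bins are damped rather than amplified to unit
   weight. Frames are shifted back by bilinear interpolation. Rotational
   or vessel-tracking registration is out of scope.
4. **Distorted-frame detection.** For each frame, the Euclidean distance
   (ED) to the pixel-wise median image of the 71 surrounding frames
   (frame included, window truncated at the sequence ends) is computed;
   Rosner's generalized extreme Studentized deviate (GESD) test on the ED
   series flags outliers — blinks and blurred frames. A user-supplied
   index list stands in for the study's manual refinement step.
5. **VP signal.** The vein region of interest (ROI; a binary mask over
   the pulsating vein segment, drawn manually in practice) is averaged
   per frame to give the raw vein pulsation signal `I_VP(n)`. The vein is
   dark, so vein collapse (minimum diameter) appears as the per-cycle
   *maximum* of `I_VP`.
6. **Normalization.** Distorted frames are replaced by 1-D cubic
   interpolation through the good samples. The low-frequency component
   `I_AVG(n)` is a centred moving average whose window spans 1.5 mean
   cardiac cycles (`N = round(1.5 * meanRR * fps)`, forced odd; 35 frames
   at a 0.93 s cycle and 25 fps). The relative signal
   `I_VPrel = I_VP / I_AVG` fluctuates around 1 and cancels any common
   illumination gain; `I_VP' = 100 * (1 - I_VPrel)` is its
   photoplethysmographic (PPG) form in percent, where each per-cycle
   *minimum* marks minimum vein volume, i.e. collapse.
7. **Collapse timing.** For each R-wave, the minimum of `I_VP'` is
   searched among frames starting within 220 ms after the R-wave (a
   window fixed from the physiological literature and exposed as a
   parameter) and refined to sub-frame precision by a parabolic fit
   through the minimum and its two neighbours. `tvc_ms` is the interval
   from the R-wave to that minimum; `tvc_rel_pct` divides by the same
   cycle's R-R interval.
8. **Cycle selection.** A cycle is excluded automatically when its search
   window contains more interpolated frames than allowed (default: none),
   when its minimum sits on the window boundary, or when listed manually.
   On 10–15 s recordings this typically leaves 5–11 usable cycles.

Summaries follow the same conventions throughout: Spearman rank
correlations (average ranks for ties, two-sided p by the t
approximation), SDRR as the sample standard deviation of R-R intervals,
and Tukey (inclusive-median) quartiles in the per-subject boxplot tables.

## The synthetic acquisition model

`sim_config()` fixes one simulated recording session. Defaults encode the
study conditions:

| parameter | default | meaning |
|---|---|---|
| `duration` | 12 s | recording length (study range 10–15 s) |
| `fs_bio`, `fps` | 1000 Hz, 25 Hz | sampling rates; `fs_bio/fps` must be an integer |
| `hr_mean`, `hr_sd` | 64, 3 bpm | resting heart rate and beat-to-beat variability |
| `rr_floor_s` | 0.55 s | lower truncation of drawn R-R intervals |
| `collapse_delay_ms` | 120 ms | true R-wave to collapse delay (observed range 60–220) |
| `pulsation_amplitude` | 0.04 | ROI-mean modulation as a fraction of baseline |
| `drift_amplitude` | 0.05 | multiplicative illumination drift (< 0.3 Hz) |
| `noise_sd` | 0.002 | additive noise, intensity units on [0, 1] |
| `frame_size` | 128 × 128 px | rendered frame geometry |

The ECG is a sum of Gaussian deflections per beat (P, QRS of ~25 ms width,
T) over slow baseline wander — the simplest morphology that exercises the
detector's filters: the size-10 median filter attenuates but cannot erase a
QRS this wide. The per-cycle vein-volume waveform is a raised cosine that
reaches its minimum (collapse) exactly `collapse_delay_ms` after each
R-wave, giving a single unambiguous extremum per cycle;
`set_collapse_delays()` overrides the delay per cycle (e.g. to tie it to
each cycle's length). Frame intensity is modelled at the frame start
rather than integrated over the 40 ms exposure; at 25 fps the difference
is second order for a waveform this smooth.

Two default choices deserve their rationale:

* **R-R floor (0.55 s).** Intervals are truncated from below so simulated
  beats respect the detector's physiological ceiling (110 bpm,
  60/110 = 0.545 s). The floor sits a few milliseconds above the
  detector's 0.545 s refractory because peak positions at 1000 Hz carry
  ~0.5 ms of quantization plus ~0.5 ms of noise-induced jitter: beats
  generated exactly at the refractory boundary would be unresolvable by
  construction, which is a property of sampling, not of the detector.
* **Noise semantics.** `noise_sd` is additive noise on whatever the
  generator emits. For the signal-level trace it plays the role of
  ROI-mean noise, and its default (0.002 = 10% of the default modulation
  amplitude) matches the recovery conditions the tests probe; when
  rendering frames the same knob is per-pixel noise, for which ~0.01 (1%
  of full scale) is a realistic camera figure — the ROI mean then averages
  it down by the square root of the ROI area (~1000 px).

The rendered video adds a static textured background (smooth shading plus
fine granular texture — the detail frame registration locks onto), a dark
sinuous vein whose local width follows the volume waveform (so the ROI
mean tracks the analytic trace), optional near-black blink frames, and
optional integer per-frame translations to exercise alignment. The
generator emits the true ROI mask, blink indices, shifts, R-times and
collapse times as ground truth.

What the generator does **not** emulate: photorealistic fundus appearance,
rotational eye movement, exposure-time motion blur, non-stationary heart
rhythm (arrhythmia), IOP/CSFP waveforms, and spatially correlated sensor
noise. Passing recovery tests therefore demonstrates correctness of the
measurement chain under the stated signal model, not robustness to every
clinical artefact.

## Numerical choices

* Images are floating point in [0, 1] after loading, whatever the source
  bit depth; 1-based frame and sample indexing throughout (the R
  convention), times in seconds, `T_vc` in milliseconds.
* All 1-D filters use reflect padding; Gaussian kernels truncate at 4
  sigma. The even-width median window sits one sample left of centre.
* Peak ties within the minimum-distance rule keep the earlier peak;
  plateaus count once, at their first sample.
* GESD defaults: `alpha = 0.05`, `max_outliers = ceil(0.1 * n_frames)`
  (blinks rarely exceed 10% of frames); zero variance stops the
  iteration. The 71-frame median window includes the frame itself — with
  70 neighbours the frame cannot shift its own median, and inclusion
  simplifies indexing.
* Distorted-frame detection assumes the ED series is roughly exchangeable
  across frames. Strong illumination drift breaks this at the sequence
  boundaries, where the truncated median window is asymmetric: boundary
  frames then show genuinely elevated ED and the test may flag them. On
  real data this is what the manual-review list is for; the package's
  distortion-recovery checks therefore run at zero drift.
* The collapse minimum is refined by a parabola only when its two frame
  neighbours exist and curvature is positive; the offset is clamped to
  half a frame. Sub-frame refinement sharpens a symmetric minimum without
  biasing it — at 25 fps the raw quantization (40 ms) would otherwise
  dominate a 60–220 ms measurand.
* Spearman p-values use the t approximation at all n (cross-checked
  against `stats::cor.test(exact = FALSE)`); p-values are reported raw,
  with an optional Holm adjustment flag, mirroring how such covariate
  screens are usually reported.

## Problem sizes in the test-suite studies

The suite validates by parameter recovery at desk scale: detector sweeps
over 10 heart rates in [50, 110] bpm; delay-recovery over
{80, 120, 180} ms × 10 seeds (≈ 290 cycles); blink recovery on 10 videos
of 250 frames at 128 × 128 px; GESD against an independent transcription
on 100 random vectors plus the canonical 54-point benchmark; and the
cycle-length independence property on 20 pooled cohorts of 13 subjects
(≈ 2 600 cycles). These sizes give Monte-Carlo error comfortably below
each check's tolerance.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(duration = 12, collapse_delay_ms = 120,
                  blink_count = 2, noise_sd = 0.01, seed = 17)
sim <- simulate_subject(cfg)
an <- analyze_simulation(sim)
glance(an)     # one-row summary: n cycles, median T_vc, SDRR, window N
tidy(an)       # per-cycle table
autoplot(an)   # PPG signal with R-waves and detected collapses
```

## Known limitations

* Translation-only alignment: rotation and non-rigid motion are not
  corrected.
* The collapse search assumes exactly one collapse per cycle within
  220 ms of the R-wave; rhythms violating this (ectopic beats) are not
  modelled and will be flagged, not repaired.
* Boundary cycles (first/last) and any cycle whose window leaves the
  recording are dropped rather than extrapolated.
* The PPG normalization assumes illumination changes are multiplicative
  and slow; fast or additive illumination artefacts land in the distorted-
  frame path instead.
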