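---
title: "Classifying movement behaviours from thigh-worn accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying movement behaviours from thigh-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actithigh)
```

## The measurement model

A triaxial accelerometer on the anterior thigh measures, in units of g,
the sum of the gravity projection onto its axes and the acceleration of
the limb. `actithigh` fixes the axis frame as U (longitudinal, positive
toward the knee; aligned with gravity when standing), V (mediolateral)
and W (anteroposterior, positive forward). Two quantities then separate
daily behaviours remarkably well:

* **orientation** — the inclination of the mean acceleration vector
  relative to +U is near 0° standing and near 90° sitting, because
  sitting brings the thigh horizontal; the signed angle in the U–W plane
  (the *forward lean*) additionally distinguishes level walking from
  stair climbing (higher thigh lift) and from cycling (strongly forward
  thigh);
* **movement intensity** — the standard deviation of the filtered
  acceleration magnitude is near zero in stationary postures and grows
  with effort, and the dominant frequency of the longitudinal axis (the
  *cadence*) marks gait.

Raw samples are low-pass filtered (4th-order Butterworth, default cutoff
5 Hz) and features are computed in 2-s windows with 1-s overlap, so each
1-s *epoch* receives the axis means, the magnitude SD (raw and
polynomial-corrected), inclination, forward lean, and the cadence from a
centred 4-s context window restricted to 0.3–4 Hz. Daily human movement
rarely exceeds 5–6 Hz, which is why sampling at 25 Hz or even 12.5 Hz
(Nyquist 6.25 Hz) suffices, and why the 5-Hz default cutoff sits below
the 12.5-Hz Nyquist limit.

The filter is applied forward–backward (zero phase), keeping features
time-aligned with video-style annotations; the magnitude response is
squared, so a tone at the cutoff is halved rather than attenuated by
3 dB. The filtering primitive uses odd-reflection padding with the DC
level subtracted per pass, making a constant signal an exact fixed point
— a property several tests rely on.

## The decision tree

Each epoch is classified by a fixed tree in this order:

1. `sd < sigma_stationary` (0.1 g): stationary — *sedentary* if
   inclination ≥ 45°, else *stand*;
2. forward lean ≥ 40° with cadence in 0.3–2.0 Hz: *cycle* (checked
   before running so intense pedalling is not swallowed by the SD rule);
3. cadence ≥ 2.5 Hz or sd ≥ 0.72 g: *run*;
4. cadence in the gait band 0.6–2.5 Hz with forward lean at or above the
   individual stairs threshold: *stairs*;
5. remaining gait-band epochs: *walk*;
6. everything else active: *move* (brief, irregular, aperiodic
   activity).

The exact constants are not fixed by the lineage's published
descriptions; they are `classifier_config()` defaults, chosen to
separate the documented signal profiles, and every one of them is a
config value so sensitivity can be explored (`cmd_sweep()` sweeps the
stairs threshold).

**The individual stairs threshold.** Walking and stair climbing differ
mainly in thigh lift, and the discriminating lean varies between people,
so the threshold is estimated per recording: over epochs that are
active, in the gait cadence band, and provisionally walking-like
(forward lean below both the cycling threshold and the 25° population
fallback), the threshold is the 95 % quantile of forward lean plus a 2°
margin. The provisional-walk pre-filter matters: without it, stair and
cycling epochs enter the quantile and push the threshold above the
stairs mode whenever stair climbing is a large fraction of locomotion
(as in a balanced laboratory script), which would misclassify stairs as
walking — precisely the failure mode the threshold exists to avoid. With
fewer than 60 qualifying epochs the population fallback is used and
flagged, modelling the uncertainty of short recordings.

Label post-processing applies a 5-epoch modal filter (ties keep the
centre label) and absorbs bouts shorter than a per-class minimum (run
2 s, stairs 4 s, cycle 15 s, others 2 s) into the longer neighbour,
earlier neighbour on ties.

## Dynamic range and the SD correction

A sensor with a narrow dynamic range clips high-intensity signals
(saturation), deflating the SD feature exactly where the run threshold
operates. `correct_sd()` applies a device-specific second-order
polynomial `max(0, c2·sd² + c1·sd + c0)` (identity `(0, 1, 0)` by
default), and `calibrate_sd_polynomial()` fits the coefficients by least
squares on clipped-vs-reference SD pairs. The correction is only
meaningful in the mild-saturation regime: once the signal is strongly
clipped the SD plateaus and the mapping to the true intensity is no
longer invertible, so fits should span intensities up to the onset of
heavy clipping, not beyond. No frequency-specific refit of the
polynomial for 12.5-Hz data is attempted.

## Two-step calibration

1. **Device autocalibration** (`autocalibrate_device()`): during still
   epochs (SD < 0.013 g) an ideal sensor measures exactly 1 g, so
   per-axis gains and offsets are estimated by iteratively regressing
   still-epoch mean vectors onto their closest points on the unit
   sphere, followed by a direct least-squares polish (the per-axis
   regression converges linearly and can stall ~5·10⁻³ short of the
   optimum). At least three still orientations more than 15° apart are
   required; otherwise the fit is underdetermined and the identity is
   returned with a warning flag. No temperature term is modelled — the
   data model carries no temperature channel.
2. **Individual calibration** (`individual_calibration()`): a pre-pass
   with default thresholds selects upright-locomotion epochs
   (walk/run/stairs); the componentwise median of their mean vectors is
   the observed thigh direction. Inverted mounting (median U < 0 over
   active epochs) is corrected by a 180° flip about W *before* the
   pre-pass, because an inverted U wraps the forward lean past 90° and
   would otherwise make gait look like cycling. The returned rotation
   maps the observed direction onto the expected locomotion posture
   `(cos ref, 0, sin ref)` with `reference_lean_deg = 20°` — the typical
   mean thigh lean during level walking — rather than onto +U itself, so
   a perfectly mounted sensor yields the identity rotation. Locomotion
   is used as the reference (rather than a scripted posture) because
   free-living data has no script; one round only, no iteration.

Calibration is applied as `rotation %*% ((sample − offset) / gain)` and
never changes the epoch count or time base.

## Clock synchronisation

Devices and cameras keep independent clocks, modelled linearly:
`t_dev = t_ref·(1 + drift_ppm·10⁻⁶) + offset_s` — the minimal model
covering a constant offset and constant-rate drift. Three deliberate
heel-drops produce unmistakable spikes; `detect_heel_drops()` clusters
|U|-threshold exceedances (default 2.5 g, above running peaks) and keeps
clusters with at least three distinct peaks. Anchors matched by order
give the coarse model (`fit_sync_model()`, exact with two anchors);
`refine_by_xcorr()` then measures the residual lag of the band-passed
(0.5–3 Hz) longitudinal axes — gait periodicity is the signal shared by
co-located devices — in 120-s windows, refits the linear model on
(window centre, lag) pairs, and keeps the refinement only when it lowers
the median absolute window lag. Windows that are flat or whose
correlation peak is below 0.2 are skipped (uncorrelated noise peaks at
≈ 0.05 for these window lengths, so 0.2 cleanly rejects spurious
refinements); if all are skipped the coarse model is returned with a
warning. The window length and band are configuration values.

## What the simulator emulates — and what it does not

`simulate_recording()` builds each behaviour as an exact unit gravity
direction at the behaviour's inclination (slow wander superimposed),
plus a cadence sinusoid applied in phase on U and W, plus white noise,
then clips through the device model. In-phase oscillation makes the
acceleration *magnitude* oscillate with the periodic amplitude, so
intensity grows with effort and range clipping visibly deflates the SD
— the property the polynomial correction targets. Defaults (inclination,
cadence, amplitude, noise): sedentary 75°/static, stand 10°/static, move
15°/0.5 Hz/0.20 g in 4-s bursts with 0.5-s pauses, walk 20°/1.8 Hz/0.35 g,
run 25°/2.8 Hz/1.2 g, stairs 35°/1.6 Hz/0.4 g, cycle 55°/1.1 Hz/0.3 g.

Two of these deserve justification. The move bursts sit at 0.5 Hz, just
below the 0.6-Hz lower edge of the gait band, because "move" is defined
as the *aperiodic-or-slow* residual class: bursts inside the gait band
would be walking by definition. And the burst amplitude is 0.20 g
(pauses 0.5 s) because a 0.15-g sinusoid has a magnitude-SD of
~0.106 g — statistically indistinguishable from the 0.1-g stationary
threshold whenever a 2-s window straddles a pause — which would violate
the design requirement that the generator's behaviours be separable
under the documented thresholds.

These are deliberately *minimal* constructions, not biomechanical gait
models: no impact transients, no soft-tissue artefact, no asymmetric
stance/swing waveforms, no postural transitions, and lying is merged
with sitting (single-sensor sit/lie discrimination is out of scope).
Passing tests on this substrate therefore demonstrate that the pipeline
implements its stated contracts — filtering, feature extraction,
thresholds, calibration, synchronisation, metrics — not that the
classifier reaches any particular accuracy on real recordings, where
class overlap is far larger. Heel-drop spikes are realised as
nearest-sample biphasic impulses (the nominal 40-ms width is narrower
than one sample period at both supported rates), and a drifted device
copy keeps its nominal grid while reading the physical signal through
the inverse clock map, so a pure offset appears as an equal
cross-correlation lag.

## Numerical choices and degenerate inputs

* Epoch windows are anchored at integer seconds; a partial trailing
  window is dropped (`floor(T) − 1` epochs for duration `T`).
* Chunked processing (`classify_recording(chunk_s =)`) filters each
  chunk with an 8-s context margin and keeps only interior epochs; the
  stairs threshold is estimated once, globally, so chunked and whole
  processing give identical labels.
* Downsampling is an anti-alias low-pass at 0.8 of the target Nyquist
  followed by linear interpolation, so non-integer rate ratios work;
  equal-rate downsampling is an exact identity.
* A zero mean vector in a window is flagged `degenerate` rather than
  given a fabricated inclination.
* `read_recording()` estimates the rate from the time span and rejects
  gaps larger than two sample periods rather than silently resampling.
* Display rounding for metric tables is half-away-from-zero at two
  decimals (`round_half_up()`); all computations keep full precision.
* Sample-level interpolation (sync, downsampling) is linear; at gait
  frequencies its error is ~10⁻³ g, which is why sample-exact round-trip
  guarantees are only made for node-aligned time shifts.

## Validation problem sizes

The test-suite and the acceptance script validate at desk scale: a
7 × 5-minute behaviour script (2 099 epochs) for end-to-end recall and
the 25-vs-12.5-Hz comparison, a 30-minute gait session for clock-sync
recovery, 406 paired epochs over amplitudes 0.3–1.6 g for the SD
polynomial, and six-orientation still sets for autocalibration. These
sizes keep the whole suite under a few minutes on one CPU while leaving
every estimate's sampling error far below the asserted tolerances.

## Known limitations

* The decision-tree constants are package defaults, not the (unpublished)
  constants of any particular production system.
* The overall F1 weighting uses a free-living time-use distribution
  (`freeliving_weights()`); with different prevalence weights the overall
  F1 changes even when per-class scores do not.
* "Move" is intrinsically a residual class; its boundary with standing
  is sensitive to the stationary threshold, exactly as in real data.
* The simulator's annotation model corrupts epochs independently; real
  rater disagreement is serially correlated around behaviour
  transitions, so simulated kappa values are optimistic at equal error
  rates.
* Sit-versus-lie discrimination, wear-time detection, energy
  expenditure, and proprietary binary formats are out of scope.
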