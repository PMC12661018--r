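# actithigh

Movement-behaviour classification from thigh-worn triaxial
accelerometry, with the full validation apparatus needed to study how
design choices — above all the sampling frequency — affect performance.

Physical-activity surveillance increasingly relies on a single
accelerometer worn on the anterior thigh: its orientation separates
sitting from standing, and its movement intensity and cadence separate
walking, running, stair climbing and cycling. `actithigh` implements an
Acti4-lineage processing chain for such recordings, plus everything
around it that a validation study needs: device and individual
calibration, multi-device clock synchronisation, annotation alignment,
classification metrics, Bland–Altman agreement analysis, and a synthetic
signal simulator so the entire stack is testable without any recorded
data. It is aimed at researchers in physical-activity epidemiology and
wearable-sensor methods.

## The algorithm

Raw samples (axes U longitudinal, V mediolateral, W anteroposterior, in
g) are low-pass filtered (4th-order Butterworth, zero phase, default
5 Hz) and summarised per 1-s epoch from 2-s windows with 1-s overlap:

- mean vector → inclination `θ = arccos(mean_U / ‖mean‖)` and signed
  forward lean in the U–W plane;
- movement intensity `σ` = SD of the filtered acceleration magnitude,
  with a device-specific second-order polynomial correction
  `max(0, c₂σ² + c₁σ + c₀)` compensating dynamic-range saturation;
- cadence `f` = dominant 0.3–4 Hz frequency of the U axis over a 4-s
  context.

A fixed decision tree labels each epoch: stationary (`σ < 0.1 g`) splits
into sedentary (`θ ≥ 45°`) vs stand; then cycle (lean ≥ 40°, f in
0.3–2 Hz), run (`f ≥ 2.5 Hz` or `σ ≥ 0.72 g`), stairs (gait-band cadence
with lean above an individually estimated threshold), walk (gait-band
cadence), else move. The walk-vs-stairs threshold is the 95 % quantile
of walking forward lean + 2°, estimated per participant with a
population fallback of 25° for short recordings. Labels are smoothed by
a modal filter and minimum-bout rules, and aggregated to minutes per
behaviour per 24 h.

Validation tools compute one-vs-all precision/recall/specificity, F1,
balanced accuracy (overall = mean per-class recall), pooled confusion
matrices, Cohen's kappa for inter-rater agreement, and Bland–Altman
bias with 95 % limits of agreement (`bias ± 1.96·SD`). Synchronisation
uses heel-drop spike anchors plus cross-correlation drift refinement
under a linear clock model.

See `vignettes/behaviour-classification.Rmd` for the full model
description, parameter rationale, and limitations.

## Worked example

Simulate a structured laboratory session (six behaviours × 1 min with
15-s standing breaks), classify it, and score against the ground truth:

```r
library(actithigh)

sim <- simulate_recording(lab_protocol_script(), fs_hz = 25, seed = 42)
sim$recording
#> <triaxial_recording> 10875 samples @ 25 Hz (435.0 s) on narrow-range, start 0 s

labels <- classify_recording(sim$recording)
attr(labels, "theta_stairs")   # individual walk-vs-stairs threshold (deg)
#> [1] 24.43116

truth <- epoch_labels(as.character(sim$truth)[seq_along(labels)])
class_metrics(confusion(truth, labels))
#>      class precision recall specificity   f1 balanced_accuracy
#>  sedentary      1.00   0.98           1 0.99              0.99
#>      stand      0.99   0.99           1 0.99              0.99
#>       walk      0.98   1.00           1 0.99              1.00
#>        run      0.98   1.00           1 0.99              1.00
#>     stairs      1.00   1.00           1 1.00              1.00
#>      cycle      1.00   1.00           1 1.00              1.00
#> overall: weighted F1 0.99, balanced accuracy 0.99, accuracy 0.99
```

The individual stairs threshold (~24.4°) sits just above the walking
forward-lean distribution, so stair climbing (thigh lifted to ~35°)
stays separable. Downsampling the same recording to 12.5 Hz
(`downsample(sim$recording, 12.5)`) and re-classifying leaves the
overall balanced accuracy essentially unchanged (0.995 at both rates on
this session) — halving the sampling frequency costs little for these
behaviours, whose dominant frequencies stay well below the 6.25-Hz
Nyquist limit.

A command-line front end wraps the same functions:

```sh
exec/actithigh simulate --out session --seed 5
exec/actithigh classify --recording session/recording.csv --out session
exec/actithigh validate --labels session/labels.csv --annotations session/annotations.csv --out session
```

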