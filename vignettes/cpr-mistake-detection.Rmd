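---
title: "Detecting chest-compression mistakes from multimodal sensor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chest-compression mistakes from multimodal sensor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Quality of cardiopulmonary resuscitation (CPR) is judged per chest
compression (CC) against well-standardised guideline indicators: the
compression **rate** should lie in 100–120 compressions/min, the **depth** in
50–60 mm, and the chest should be **released** almost completely between
compressions. Two further mistakes — failing to lock the elbows and pressing
with the arms instead of the trunk's body weight — are invisible to training
manikins and traditionally caught only by human instructors.

`cprtutor` implements a complete mistake-detection pipeline over multimodal
recordings of compression-only training sessions: a depth-camera skeleton
stream (15 joints, 3-D positions, ~30 Hz), an arm-worn band with 8
electromyography (EMG) channels plus accelerometer/gyroscope/orientation
(~100 Hz), and a per-compression annotation stream from a training manikin.
Each compression is segmented out, labelled against the guideline
thresholds, resampled to a fixed number of time bins, and classified with a
recurrent (LSTM) network — one classifier per indicator.

Because no public corpus of such recordings exists, the package ships a
synthetic session generator with controllable mistake injection and known
per-compression ground truth. All quantitative claims made by the test suite
are claims about this generator's stated world, not about human data.

# Labelling scheme

Rate and depth are ternary: class 0 below the guideline interval, 1 within,
2 above. Release, arm locking and body weight are binary (1 = correct).
Two decisions deserve note:

* **Interval bounds are inclusive at both ends.** A measured depth of
  exactly 60.000 mm is in-range (class 1). Inclusive bounds are the only
  convention consistent with reference per-compression tables in which a
  60.000 mm compression is labelled correct while 60.91 mm is labelled too
  deep.
* **The release threshold defaults to 5 mm**, not the 10 mm a literal
  "0–1 cm" guideline reading would give. Reference annotations label a
  6.11 mm residual as *not released* and 4.00 mm as *released*, which only a
  threshold in (4.00, 6.11] mm explains; 5 mm is the conventional
  manikin cutoff inside that range. Both the intervals and the threshold are
  configurable via `guideline_thresholds()`.

Arm locking and body weight have no instrumented measurement rule; the
labeller validates and propagates those annotations untouched.

# The synthetic session model

The generator (`simulate_session()`) is **invented plumbing, not validated
biomechanics**. Its purpose is testability: every signal is a deterministic,
differentiable function of a known per-compression ground truth, so
downstream recovery can be checked exactly. The model:

* Each compression cycle `c` has period `60/rate_c` s and produces a
  raised-cosine displacement pulse rising from the residual `release_c` (mm)
  to the peak `depth_c` (mm) and back. A raised cosine (rather than a pure
  sine) makes depth and release independently controllable.
  Per-compression values are Gaussian draws around the targets
  (`rate_jitter_cpm`, `depth_jitter_mm`, `release_jitter_mm`; defaults
  3 cpm / 2 mm / 1 mm, a plausible within-subject spread for a trained
  provider).
* Hands and wrists track the negated displacement; shoulders and spine track
  `-alpha * d(t)` with `alpha = 1` when body weight is used and `0.3` when
  the arms do the work; elbows stay collinear between shoulder and hand when
  locked, else dip an extra `0.25 * d(t)`. Heads, hips and ankles are
  static (they exist so the exclusion rule downstream has material to act
  on). Skeleton coordinates are in metres.
* Each EMG channel fires one rectified Gaussian burst per cycle, amplified
  2x when body weight is *not* used (arm-muscle compensation). The
  accelerometer is the discrete second derivative of the hand trajectory (in
  g), the gyroscope the first derivative mapped through a 0.3 m forearm, and
  the orientation quaternion tilts slightly with displacement. Note that
  velocity scales with `depth x rate` and acceleration with
  `depth x rate^2`, which is what makes the rate class recoverable after
  time-normalised resampling removes absolute duration.
* All channels are sampled at their device rates (defaults 30 / 100 Hz —
  assumptions, configurable) with additive Gaussian noise. `sensor_noise_sd`
  is expressed in skeleton units (metres; default 0.005, i.e. 5 mm, a
  realistic depth-camera jitter) and scaled into EMG/inertial units by named
  constants. Every model constant lives in `cpr_model_constants()` rather
  than being hard-coded.
* The recording starts and ends with a rest period (`lead_in_s`, default
  1 s) during which the chest is fully released, giving baseline estimation
  a reference and making the final release observable.

The emulated manikin (`manikin_emulate()`) recovers per-cycle depth, rate
and release from a displacement trace, upsampling it to a 1 ms grid with a
cubic spline before extracting extrema (direct 30 Hz sampling could miss a
peak by ~0.5 mm; the spline reduces that to ~0.01 mm). When the input trace
is a noisy camera channel, its baseline (estimated as the maximum observed
height) inflates with noise — which is precisely why ground-truth labels
come from the manikin, not the camera.

What the generator does **not** emulate: postural drift, fatigue trends,
occlusion and skeleton-tracking dropouts, EMG crosstalk, inter-subject
anatomy, rescue breaths or multi-rescuer hand-offs. A green test therefore
establishes that the pipeline's machinery is correct and that the
classification task is learnable when the classes are separable — not that
the reported accuracies transfer to human recordings.

# Preprocessing

`sessions_to_tensor()` implements the fixed routine: stack all annotation
intervals into one table (with the absolute session date-time
disambiguating sessions that all start at t0 = 0); consolidate sensor
streams into one time-indexed attribute table; mask it with the compression
intervals; resample each masked series to `S = 8` equal-duration bins; stack
into an `N x S x Q` tensor scaled to [0, 1] per attribute. Choices where
the routine was underdetermined:

* **Half-open intervals `[start, end)`** — prevents a boundary update being
  assigned to two compressions. Non-overlap is verified, not assumed.
* **Duplicate timestamps: keep the first occurrence** (per recording).
* **Sparse semantics:** where a device did not update, the value is *absent*
  (`NA`), not zero — zeros from non-updates would corrupt bin means. A dense
  zero-filled export (`as_dense_attribute_table()`) exists for
  interoperability.
* **Attribute hygiene:** names are stripped of underscores and other special
  characters; columns whose running total is zero are dropped as
  uninformative; columns matching an excluded joint (default ankles, hips,
  head — kneeling performers, wandering gaze) are dropped. The surviving
  attribute count `Q` is data-dependent by construction.
* **Resampling = per-bin mean,** with empty bins filled by linear
  interpolation between the nearest non-empty bins and nearest-value
  extension at the edges. The bin-mean is checked exactly against a
  brute-force oracle in the tests. An attribute with no updates at all
  inside an interval is filled with 0 after a warning; an interval empty in
  *every* attribute is an error surfaced to the caller.
* **Zero-range attributes scale to 0**, keeping the tensor finite.
* **Scaling is fitted on the full tensor before the train/test split.** This
  replicates the upstream routine's stated order and is, strictly, a small
  information leak; `sessions_to_tensor(scale = FALSE)` plus per-partition
  scaling is the clean alternative for anyone who wants it.

Compression duration is deliberately *not* a feature: resampling to a fixed
number of bins removes absolute time, matching the reference routine.

# The classifier

One LSTM per indicator: input `S x Q`, one hidden layer of 128 units, dense
softmax output with 2 or 3 units, sparse categorical cross-entropy,
66/33 random-shuffle split (test size `round(0.33 * N)`, which is the only
rounding that reproduces the canonical 3520/1734 split of N = 5254).

No deep-learning backend exists in the deployment environment, so the LSTM
(forward pass, backprop-through-time, Adam) is implemented in vectorised
base R (`R/lstm.R`). At these dimensions full-batch matrix algebra is cheap;
30 epochs over ~1100 training compressions take ~25 s on one CPU. Unstated
training details were fixed as: Adam with learning rate 1e-3, minibatch 32,
Glorot-uniform input weights, block-orthogonal recurrent weights,
forget-gate bias 1. All are recorded in the run manifest.

There is **no early stopping**: the full epoch budget runs (30 epochs for
ternary targets, 100 for binary) and the *overfitting point* is read
retrospectively as the 1-based epoch of minimum validation loss (earliest on
ties), via `detect_overfit_epoch()`. Class imbalance is left unhandled,
matching the reference protocol. ROC-AUC is computed rank-based
(Mann–Whitney with midranks, so a constant scorer scores exactly 0.5) for
binary targets and reported as not applicable for ternary ones. The split is
not stratified and not per-participant; a per-participant split would be the
stricter generalisation protocol and is left to the user.

# Acceptance surface

The accuracies reported in the source study (86.5 % rate, 71.8 % depth,
73.9 % release, 93.4 % arms, 97.8 % body weight) were measured on private
human recordings and are not reproducible. The substitute criterion is
*parameter recovery*: on a simulated cohort (16 sessions x 60 s,
~1700 compressions) whose class-conditional parameters sit at least two
jitter SDs apart (rate levels 80/110/130 cpm, depth 40/55/65 mm, release
2/10 mm), every one of the five classifiers must reach >= 0.95 test
accuracy within its epoch budget, and training on permuted labels must fall
back to the majority-class rate +- 0.05. A single permuted run is a noisy
estimate of that null accuracy (SD ~ 0.03 at this test-set size), so the
suite averages a few permutation replicates — a lower-variance estimate of
the same quantity, not a relaxation of the band — and runs the null for one
ternary and one binary target to stay inside the time budget.

# Known limitations

* The skeleton stream emits 45 attributes (15 joints x X/Y/Z). The
  reference device reports 60 "position features" for 15 joints; the fourth
  per-joint feature is unnamed upstream and was not invented here.
* The archive manifest layout (`session.json` + one
  `<applicationName>.json` per recording) is this package's own convention;
  only the per-recording JSON dialect is externally specified. Zip archives
  are read; directories are written.
* Device sampling rates (30 / 100 Hz) are assumptions, kept configurable.
* The simulator's constants (shoulder coupling 0.3/1.0, elbow dip 0.25, EMG
  gain 2x) are chosen for separability and named in
  `cpr_model_constants()`; they carry no physiological authority.
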