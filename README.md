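# cprtutor

Mistake detection for CPR training from multimodal sensor data.

Good cardiopulmonary resuscitation is judged per chest compression (CC):
guideline-correct compressions run at **100–120 compressions/min**, reach
**50–60 mm** depth, and release the chest almost completely (residual
≤ 5 mm) between presses. Training manikins measure those three indicators;
two further mistakes — unlocked elbows and pressing with the arms instead of
the body weight — are normally caught only by human instructors.

`cprtutor` is an R implementation of a full detection pipeline over
multimodal recordings (depth-camera skeleton at ~30 Hz, an arm band with
8 EMG channels plus inertial sensors at ~100 Hz, and per-compression manikin
annotations):

1. **Session I/O** — read/write archives of timestamped JSON sensor frames
   and annotation intervals (`read_session()`, `write_session()`,
   `apply_offset()` for manual time alignment).
2. **Simulation** — a kinematic generator of synthetic sessions with known
   ground truth and controllable mistake injection
   (`simulate_session()`, `simulate_cohort()`), plus a manikin emulator
   deriving per-compression depth/rate/release from a displacement trace
   (`manikin_emulate()`). No public corpus of real recordings exists; this
   is the package's test bed.
3. **Labelling** — guideline classes per compression: rate and depth are
   ternary (0 = below the interval, 1 = within, bounds inclusive,
   2 = above), release/arms/body weight binary (`label_compressions()`).
4. **Preprocessing** — consolidate streams into a sparse time-indexed
   attribute table, mask it with the compression intervals (half-open
   `[start, end)`), resample every compression to S = 8 equal-duration bins
   (bin means, linear interpolation of empty bins) and stack into an
   `N × S × Q` tensor min–max scaled to [0, 1] (`sessions_to_tensor()`).
5. **Classification** — one recurrent (LSTM, 128 hidden units) classifier
   per indicator, sparse categorical cross-entropy, 66/33 random split
   (`train_classifier()`, `evaluate_classifier()`,
   `detect_overfit_epoch()`). The LSTM is implemented in vectorised base R —
   no deep-learning backend is required.
6. **Pipeline** — `run_pipeline(run_config(...))` orchestrates everything
   reproducibly from one seed and writes artifacts plus a manifest.

See `vignettes/cpr-mistake-detection.Rmd` for the model, its assumptions and
the design decisions.

## Worked example

Simulate a session in which the provider compresses **too fast**
(130 compressions/min against the 100–120 guideline), label the manikin's
per-compression measurements, and build the feature tensor:

```r
library(cprtutor)

p <- simulation_params(rate_cpm = 130, depth_mm = 55, release_mm = 2,
                       duration_s = 30, seed = 42)
sim <- simulate_session(p)
lab <- label_compressions(sim$ground_truth)
head(lab[, c("start", "end", "compDepth", "compMeanRate", "compRelease",
             "classRate", "classDepth", "classRelease")], 3)
#>   start   end compDepth compMeanRate compRelease classRate classDepth classRelease
#> 1 1.000 1.447     53.87        134.1       2.363         2          1            1
#> 2 1.447 1.902     55.81        131.9       1.894         2          1            1
#> 3 1.902 2.348     54.81        134.5       4.018         2          1            1

table(classRate = lab$classRate)
#> classRate
#>  2
#> 64

summarize_annotations(sim$ground_truth)
#>      indicator    mean    std    min     max
#> 1    compDepth  54.747 1.8651  49.01  58.697
#> 2 compMeanRate 130.010 3.0001 122.68 138.106
#> 3  compRelease   2.023 0.9576   0.00   4.287

sessions_to_tensor(sim$session)$tensor
#> <feature_tensor> 64 compressions x 8 bins x 48 attributes
```

Every compression is (correctly) labelled class 2, "too fast", while depth
and release stay in range; the 30 s session yields 64 compressions, each an
8-bin × 48-attribute slice of the tensor a classifier trains on. End to end
with five classifiers:

```r
cfg <- run_config(cohort = simulate_cohort(n_sessions = 16, duration_s = 60,
                                           seed = 11),
                  seed = 11, output_dir = "run1")
report <- run_pipeline(cfg)   # ~5 min on one CPU (binary targets: 100 epochs)
```

A command-line front end with `inspect`, `simulate`, `label`, `prep` and
`run` subcommands lives at `inst/cli/cprtutor.R`
(`system.file("cli", "cprtutor.R", package = "cprtutor")`).

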