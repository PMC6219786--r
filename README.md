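# shakestep

Step counting from pocket-worn smartphone accelerometry with a tunable
"shake-service" event detector, plus the calibration and validation
machinery to study it.

Walking speed — step length × step count / time — is a powerful clinical
marker, but the phone pedometers that could measure its step-count
ingredient at the point of care are non-tunable and notoriously
inaccurate over short courses and at slow gait speeds (< 1 m/s), the
speeds of the patients who matter most. `shakestep` is for researchers in
digital health and gait analysis who want a transparent, adjustable
alternative and a principled way to tune and evaluate it.

## What it implements

**The detector.** A trace of tri-axial accelerations is resampled to the
detector rate (10 Hz); an event (step) is registered at sample *i* when

```
max(|Δax_i|, |Δay_i|, |Δaz_i|) > sensitivity      (m/s²)
and   t_i − t_last_event ≥ refresh_ms / 1000       (refractory window)
```

Two knobs only: *sensitivity* (acceleration-delta threshold) and
*refresh time* (refractory period). Crossings inside the refractory
window are discarded; the detector sees only deltas, so gravity and
sensor bias cancel.

**Calibration.** A sensitivity × refresh grid is evaluated per gait
speed (slow < 1 m/s, normal > 1 m/s) over repeated trials; per-setting
accuracy is the mean absolute step difference |counted − observed|;
settings are compared by negative binomial regression of that difference
fitted by GEE (exchangeable working correlation, clustered on
participant, robust SEs) against the empirically best setting as
referent, reporting incidence rate ratios; the per-speed minimizer is
selected. Because vertical acceleration amplitude rises linearly with
walking speed, slow walking genuinely needs a lower sensitivity — the
pipeline recovers that ordering.

**Validation.** A simulated cohort walks 6/10/20 m courses at both
speeds on two platforms, three trials each; the calibrated detector is
contrasted with a fixed-parameter baseline counter (a stand-in for
non-tunable native pedometer software) in one NB-GEE model per
platform × speed × distance cell — 12 models — reported as
mean ± SD per method, IRR with 95% CI, and p-values.

**The simulator.** Synthetic pocket-worn accelerometry with exact
ground-truth step counts: gravity + speed-proportional sinusoid at the
step frequency + harmonics + ramps + per-trial pocket rotation + noise;
`observed_steps = ceiling(distance / step_length)` (the walker stops on
the crossing step). The NB-GEE estimator (`nbgee()`) is implemented in
the package and cross-checked against `MASS::glm.nb` in the tests.

## Worked example

```r
library(shakestep)
cfg <- run_config(seed = 7, out_dir = "demo-run",
                  calibration_participants = 5,
                  validation_participants = 12)
res <- run_pipeline(cfg, verbose = FALSE)
res$calibration
#> Calibration result
#>   slow: selected 1.5/450 (mean abs diff 5.07 steps over 30 obs/setting)
#>   normal: selected 2/400 (mean abs diff 1.43 steps over 30 obs/setting)
res$report[, c("platform", "speed_category", "distance_m",
               "mean_cmp", "mean_ref", "irr", "p_value")]
#>    platform speed_category distance_m mean_cmp mean_ref   irr  p_value
#> 4   android           slow          6    0.944    9.333 0.101 1.92e-45
#> 5   android           slow         10    2.500   15.333 0.163 6.85e-57
#> 6   android           slow         20    5.194   30.167 0.172 5.70e-22
#> ...
```

Reading the output: calibration picked sensitivity 1.5 for slow walking
and 2.0 for normal (slow ≤ normal, as the speed–amplitude link
predicts). In the validation report, `mean_cmp` is the shake detector's
mean absolute step difference, `mean_ref` the fixed baseline's, and
`irr` their ratio: at slow speed the baseline's frozen threshold sits
above the walking amplitude, so it misses most steps (errors of 9–30
steps) while the calibrated detector stays within a few steps —
IRR ≈ 0.1–0.2, p ≪ 0.001 in every slow cell. At normal speed both
methods are accurate and mostly indistinguishable.

Artifacts (trial tables, records, `calibration.json`, validation report
as CSV/JSON/Markdown) land in `out_dir`, stamped with the seed and a
configuration hash; re-running the same config reproduces them byte for
byte. A thin CLI over the same functions is in
`inst/cli/shakestep.R` (subcommands `simulate`, `detect`, `calibrate`,
`validate`, `report`, `run`).

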