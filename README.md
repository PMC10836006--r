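# tugfall

Fall-risk discrimination from instrumented Timed Up and Go (TUG) tests in
community-dwelling older adults.

The TUG — rise from a chair, walk 3 m, turn 180°, walk back, sit down — is
a standard clinical mobility screen. Instrumenting it with a lumbar-worn
IMU (tri-axial acceleration V/ML/AP, angular velocity yaw/pitch/roll at
5 Hz) and a depth camera (25 skeletal key points per frame) yields a rich
kinematic recording. `tugfall` implements the complete analysis chain for
asking which extractable parameters separate high- from low-fall-risk
adults (risk defined by a Berg Balance Scale cutoff, low risk iff
BBS > 50):

1. **Synthetic data** (`simulate_trial()`, `sample_cohort()`) — seeded
   trials with ground-truth phase boundaries and two-cohort gait contrasts
   (step length 0.37 vs 0.31 m, step width 0.13 vs 0.16 m, turn-to-sit
   peak yaw 161.3 vs 122.3 deg/s, opposite-signed turn pitch drift, ...).
   No public recording set exists for this protocol, so the generator is
   first-class, tested code: every downstream stage is validated by
   parameter recovery.
2. **Segmentation** (`segment_subtasks()`) — partitions the recording into
   sit-to-stand, walk forward, turn, walk back, turn-to-sit using yaw and
   pitch angular velocity only: sitting is quiescent (activity threshold
   `baseline mean + 4 SD`), pitch bursts at the transfers, the two largest
   smoothed |yaw| peaks anchor the turns, each event extends to 20 % of
   its peak. All thresholds are relative, so boundaries are invariant to
   gyro rescaling.
3. **Features** (`extract_features()`) — the 142-parameter vector:
   8 temporal (subtask durations and percentages of duration), 3×22
   acceleration and 3×18 angular-velocity statistics (max, min, median,
   range, RMS, signed CV, and jerk = successive absolute differences of
   acceleration, in acceleration units), 10 key-point parameters (legs and
   knee angles from the joint vectors; step count, step length = 6 m /
   steps, step duration, step width), TUG duration, and age / gender /
   assistance.
4. **Statistics** (`compare_groups()`, `screen_large_effects()`,
   `univariate_logistic()`, `ablation()`) — Shapiro–Wilk-gated pooled
   t-test / Mann–Whitney U (Fisher for binaries) at α = 0.05; Cohen's d
   with the (n−1)-weighted pooled SD, screened at d > 0.8; logistic
   regression with Wald CIs; and the three-feature-set sensor ablation
   (IMU vs depth camera vs combined) compared by in-sample AUC.

## Worked example

```r
library(tugfall)
cfg <- run_config(n_low = 26, n_high = 15, seed = 7,
                  out_dir = file.path(tempdir(), "demo"))
res <- run_experiment(cfg)

head(res$screened[, c("parameter", "test_used", "p_value", "cohens_d")], 5)
#>                       parameter    test_used  p_value cohens_d
#>           gyr_median_pitch_turn            t 7.71e-21    5.971
#>           temporal_tug_duration            t 4.64e-09    2.427
#>               gyr_cv_pitch_turn mann_whitney 1.41e-07    3.408
#>  temporal_duration_sit_to_stand            t 1.53e-06    1.835
#>           acc_rms_V_turn_to_sit            t 1.89e-06    1.814

as.data.frame(res$ablation)
#>  feature_set n_features   auc
#>          IMU          3 0.926
#>  DepthCamera          2 0.908
#>     Combined          5 0.974
```

The screened table lists the parameters significant at p < 0.05 with a
large effect (d > 0.8), ordered by p — on this synthetic 26/15 cohort the
turn pitch median/CV (the pelvic-drift signature), turn-to-sit vertical
acceleration and yaw statistics, step width/length and assistance all
surface, mirroring the kind of parameters such a study reports. The
ablation shows the two sensors are complementary: the combined logistic
model's in-sample AUC (0.974) exceeds either single-modality model.

`res$recovery` compares each profile-controlled parameter's recovered
group mean with the generating value (z-scores and a 2-SE verdict) — the
package's substitute for ground truth on real cohorts.

A command-line wrapper covers the same stages:

```sh
Rscript inst/exec/tugfall segment --imu S001_imu.csv --out segments.json
Rscript inst/exec/tugfall extract --imu S001_imu.csv --skeleton S001_skeleton.csv \
        --segments segments.json --out features.csv
Rscript inst/exec/tugfall analyze --features cohort_features.csv --out report/
Rscript inst/exec/tugfall run --config run.json
```

Exit codes: 0 success, 2 validation error, 3 stage failure.

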