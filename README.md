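# bpshoulder

Musculoskeletal shoulder loads during bench-press technique variations.

The barbell bench press loads the shoulder girdle differently depending on
how it is performed: grip width (1, 1.5 or 2 bi-acromial widths, BAW),
shoulder abduction angle (45°, 70°, 90°) and scapula pose (neutral,
retracted, released) all change the reaction forces transmitted through the
glenohumeral (GH) and acromioclavicular (AC) joints — forces that have been
linked to distal clavicular osteolysis, glenohumeral instability and
rotator-cuff overuse. `bpshoulder` implements a complete, tested analysis
chain for this question, aimed at biomechanics researchers and sports
scientists who want to study shoulder loading from motion-capture and
instrumented-barbell recordings, or to prototype such studies on synthetic
cohorts before collecting data.

## What the package computes

Given 100 Hz marker trajectories, a 48 Hz per-hand mediolateral barbell
force channel (with a shared sync pulse) and scapula pointer calibrations,
the pipeline:

1. **Preprocesses** the raw streams: 4th-order zero-phase Butterworth
   low-pass at 6 Hz, linear up-sampling to 100 Hz, pulse synchronization,
   spline/rigid-body marker gap filling, scapula landmark reconstruction by
   per-coordinate linear regression on bench height, and assembly of the 3D
   hand force (vertical share fixed at `m g / 2 = 78.48 N` per hand for the
   16 kg bar).
2. **Fits a reduced shoulder-girdle model** (thorax–clavicle–scapula–
   humerus–forearm, 10 rotational coordinates, 18 aggregate muscle bundles)
   to each subject by landmark scaling, then tracks each trial by inverse
   kinematics: per frame, `q* = argmin_q Σ_m w_m ‖x_m − x̂_m(q)‖²`.
3. **Resolves the muscle redundancy** frame by frame by a minimal-effort
   quadratic program with a glenohumeral stability constraint:

       min_a Σ_i a_i²
       s.t.  Σ_i r_ij (a_i F_max,i + F_pass,i) = M_j   (moment balance)
             0 ≤ a_i ≤ 1,  |a_i(t) − a_i(t−dt)| ≤ dt/τ  (rate bounds)
             θ(R_GH) ≤ θ_max                            (stability cone)

   where the GH reaction `R_GH` is affine in the activations and must stay
   inside an elliptical cone around the axis from the humeral-head center
   to the glenoid center (otherwise humeral-head stabilizers such as the
   rotator cuff are recruited).
4. **Decomposes the joint reactions**: GH and AC forces split into a
   compression component along the joint axis and anterior–posterior /
   superior–inferior shear, with `‖R‖² = comp² + shear_ap² + shear_si²`.
5. **Compares conditions statistically**: every outcome is normalized to a
   101-point press cycle (0% barbell top, 50% lowest point, 100% top) and
   fed to a two-level random-effects analysis — within-subject OLS at each
   phase node over the factorial design (27 columns: 6 main dummies, 12
   two-way, 8 three-way interactions), then a one-sample sign-flipping
   permutation t-test (SnPM) across subjects with family-wise control by
   the max-statistic over the 101 nodes, and hierarchical pruning of
   non-significant interaction tiers.

Because no public recordings exist for this protocol, the package ships a
first-class synthetic-data module that generates subjects
(height 1.80 ± 0.10 m, mass 87 ± 8 kg), the full 3 × 3 × 3 technique grid
(21 performed conditions; narrow-grip/high-abduction cells are excluded as
unsafe), and raw trial recordings with the measurement artifacts the
pipeline must handle (marker noise and gaps, stream clock offsets, large
between-subject spread in mediolateral force).

## Worked example

```r
library(bpshoulder)

sub   <- generate_subject(7)
grid  <- technique_grid()
cond  <- grid[grid$id == "g2_a70_neutral", ]   # wide grip, 70 deg abduction
trial <- simulate_trial(sub, cond, n_reps = 2, seed = 7,
                        noise = list(lateral_frac = 0.30))  # +30% lateral
calib <- generate_scapula_calibration(sub, seed = 7)
clean <- preprocess_trial(trial, calib)

model   <- scale_model(load_model(), sub, generate_static_markers(sub))
posture <- inverse_kinematics(model, clean$markers, stride = 10)
posture
#> Posture series: 88 frames, 10 coordinates
#>   marker residual RMS: median 0.93 mm, max 1.60 mm

fit <- rmr_solve(model, posture, clean$force)
fit
#> Muscle redundancy solution: 88 frames, 18 bundles
#>   feasible frames: 88/88
#>   peak GH reaction: 991 N; peak AC reaction: 644 N
```

The marker residual (~1 mm) reflects the injected measurement noise; all
frames satisfy moment balance and the stability cone; peak GH/AC reactions
of ~991/644 N are the model's estimate for this wide-grip trial with a
laterally directed hand force of 30% of the 78.48 N vertical share.
`summary(fit)` tabulates per-bundle peak activations (here pectoralis
0.11–0.24, rotator cuff below 0.08), `coef(fit)` returns the full
activation matrix and `plot(fit)` the activation or reaction traces.

A full cohort analysis, ending in Table-1/Table-2-style summaries and the
SnPM cluster table per outcome, is one call:

```r
run <- run_pipeline(pipeline_config(seed = 1, n_subjects = 10, n_reps = 2,
                                    out_dir = "bp_run"))
run$cluster_table      # significant phase windows per term and outcome
pipeline_report("bp_run")  # 8-panel JRF figures per factor + tables
```

On a 10-subject synthetic cohort this reproduces the expected mechanics:
the wide-grip (2 vs 1.5 BAW) dummy shows a positive significant cluster on
AC compression across the loaded mid-cycle, abduction effects are confined
to the cycle ends, and a mediolateral force-direction sweep
(`force_direction_sweep()`) shows GH and AC loads minimized for laterally
directed hand forces.

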