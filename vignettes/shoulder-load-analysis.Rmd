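---
title: "Modeling shoulder loads across bench-press technique variations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling shoulder loads across bench-press technique variations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the assumptions behind them, the parameters that
matter, what the synthetic data do and do not emulate, and the numerical
and design choices made where the problem left them open.

## 1. The question and the measurement setup

Bench-press technique varies along three factors: grip width (1, 1.5, 2
bi-acromial widths), shoulder abduction angle at the bottom position (45°,
70°, 90°) and scapula pose (neutral, retracted, released). The full
3×3×3 grid has 27 cells; combinations of the narrow 1 BAW grip with 70° or
90° abduction put the shoulder in an unsafe position and are excluded
(6 cells), leaving 21 performed conditions. The quantity of interest is the
joint reaction force (JRF) in the glenohumeral (GH) and acromioclavicular
(AC) joints over the press cycle, split into compression and shear, because
those components connect to specific injury mechanisms: AC compression to
distal clavicular osteolysis, GH shear and rotator-cuff demand to
instability and cuff overuse.

The assumed instrumentation is an optical marker system at 100 Hz (14 bony
landmarks, a 3-marker acromion cluster, two barbell ends) and an
instrumented barbell measuring the per-hand mediolateral force at 48 Hz,
the two streams joined by a shared pulse. The vertical hand force is not
measured; it is taken as the gravity share of the 16 kg bar,
`16/2 × 9.81 = 78.48 N` per hand. The scapula cannot be tracked directly;
its three landmarks (trigonum spinae, angulus acromialis, angulus inferior)
are pointered relative to the acromion cluster at the up/mid/down bench
positions (height fractions 1, 0.5, 0), separately for neutral and
retracted poses.

## 2. The synthetic-data generator

No recordings are distributed, so the generator is a first-class module
that produces the raw inputs with the statistical structure the analysis
assumes. Its defaults are the study conditions, fixed once:

* **Cohort**: height ~ N(1.80, 0.10) m, mass ~ N(87, 8) kg, bi-acromial
  width ~ 0.22·height + N(0, 0.015) m; segment lengths from height by a
  standard proportion table (upper arm 0.186·H, forearm 0.146·H).
* **Cycle**: 2 s descent + 2 s ascent per repetition (no tempo was
  prescribed; this is a typical controlled training tempo), 3 repetitions
  per condition in the recording protocol (the demo pipeline uses 2).
* **Kinematics**: the subject's true model is driven through the cycle by
  the elbow-flexion profile of the condition; at every frame the humeral
  elevation dip is solved in closed form so the hand stays at half the
  grip width. The glenohumeral Euler sequence used here keeps the elbow
  flexion axis horizontal with zero axial rotation, which makes that
  closed form exact and keeps the forearm swinging in a vertical plane —
  the bar path is vertical, as in a real press. Scapula pose enters as
  coordinate offsets (retraction +0.18 rad with clavicle retraction;
  released as a tilt/rotation offset) plus a small cycle-coupled motion.
* **Measurement artifacts**: 1 mm Gaussian marker noise (typical
  opto-electronic precision), optional marker gaps, a uniform ±0.45 s
  clock offset between the streams with the pulse edge falling on a sample
  of each stream's own clock, and a mediolateral force built from a
  subject-level propensity ~ N(0.24, 0.70) (fraction of the 78.48 N
  vertical share) plus condition shifts (retracted +0.21, wide grip +0.11,
  released −0.05, 45° +0.06, narrow grip +0.03), per-repetition
  variability, a slow within-cycle wiggle and 1 N white noise. The large
  between-subject spread is deliberate: some synthetic subjects push
  medially, as observed in real athletes.

What the generator does **not** emulate: soft-tissue artifact (markers are
rigid on segments; the pointer-calibration artifact slope exists but
defaults to zero), left–right asymmetry (the left-side markers are mirrors
of the right), barbell bending/vibration, fatigue or learning across
repetitions (i.i.d.), and EMG. Passing tests therefore demonstrate that the
pipeline is *correct under its own assumptions*, not that those
assumptions hold for any particular laboratory.

## 3. Preprocessing

* **Filtering**: 4th-order zero-phase Butterworth, 6 Hz cutoff, on the
  force channel. The forward–backward pass is implemented with
  odd-reflection padding (3 filter orders) and a DC-matched initial state,
  so constants are reproduced to machine precision and the two-pass gain
  at the cutoff is the analytic |H|² = 1/2.
* **Synchronization**: the rising pulse edge is located in each stream,
  the force clock shifted so the edges coincide, and the force linearly
  resampled onto the 100 Hz marker clock. Because each device latches the
  pulse on its own sample clock, the residual misalignment stays below one
  marker frame.
* **Gap filling**: NA runs up to 10 frames (0.1 s) are filled — by the
  rigid transform of the marker's group when ≥3 sibling markers are
  visible (exact on rigid motion), otherwise by natural cubic splines.
  Longer gaps set the trial's exclusion flag rather than raising an error,
  mirroring how real trials are dropped.
* **Scapula reconstruction**: for each landmark coordinate, a linear
  regression of the calibration offsets on height fraction is evaluated at
  the frame's normalized barbell height (computed per repetition between
  that repetition's bottom and top — the mid-trial height fraction is not
  prescribed anywhere, so this is our choice) and mapped through the
  cluster pose.
* **Cycle segmentation**: repetition bottoms are topographic-prominence
  minima of the barbell height (default prominence 0.05 m); each
  repetition runs from the preceding to the following height maximum. The
  phase map is piecewise linear in time with the bottom at exactly 50%.

## 4. The reduced shoulder-girdle model

The model is a reduced parameterized analog, not a copy of any published
model file: thorax (root), clavicle (2 DOF sternoclavicular), scapula
(3 DOF acromioclavicular, kinematically driven by the reconstructed
landmarks during tracking), humerus (3 DOF ball), forearm (elbow flexion +
pronation); 18 straight-line aggregate muscle bundles (5 rotator cuff, 2
pectoralis, 3 deltoid, serratus, 2 trapezius, latissimus dorsi, teres
major, triceps long head, monoarticular elbow extensor and flexor). Two
modeling points deserve emphasis:

* the **glenoid axis** (humeral-head center → glenoid center) carries the
  anatomical ~35° anteversion of the scapular plane. This matters: with a
  purely medial axis the supine press load would be almost pure shear and
  no activation pattern could satisfy the stability constraint.
* **latissimus dorsi and teres major** are included because they are the
  only bundles with a humeral depression moment at overhead postures; the
  narrow-grip lockout is torque-infeasible without them.

Subject scaling multiplies each segment's geometry by the ratio of
measured to generic landmark distances at a static posture and masses by
the body-mass ratio; optimal muscle path lengths are recalibrated on the
scaled geometry at the reference posture. Muscle force–length/velocity
scaling of the active part is omitted (the 16 kg load is light and the
tempo slow); passive forces use an exponential above slack length.

Inverse kinematics is a damped Gauss–Newton per frame with an analytic
Jacobian (`dx/dq_j = a_j × (x − c_j)` for points distal of coordinate j),
warm-started from the previous frame and clamped to joint ranges. On
noise-free self-generated markers it recovers the generating coordinates
to machine precision; with 1 mm marker noise the residual RMS is ~1 mm.
Inverse dynamics is quasi-static by default (the cycle is slow; the
translational-inertia option changes moments by <5%), with gravity on all
arm segments.

## 5. The redundancy solver and the stability cone

Per frame the solver minimizes Σa² under (i) moment balance on the solved
coordinates, (ii) activation bounds [0, 1] intersected with rate bounds
from first-order activation dynamics (τ_act = 10 ms, τ_deact = 40 ms),
and (iii) the GH stability cone. The cone is elliptical, with half-angle
tangents `radius/depth` from the configured glenoid effective radii
(15 mm AP, 19 mm SI, labrum included) and the 25 mm head-to-glenoid
distance. It is enforced as a *hard* constraint through its supporting
hyperplanes (48 facets by default), which keeps the per-frame problem a
convex QP solved by an active-set method; the facet approximation admits a
cone overshoot of order (π/48)² ≈ 4·10⁻³ rad². Frames are solved in time
order with warm starts.

Balanced coordinates are the three GH rotations' first two (plane of
elevation and elevation) and elbow flexion. Axial humeral rotation is
deliberately **not** balanced: straight-line aggregate bundles have
unreliable axial moment arms, and in reality part of the small (~2–3 N m)
axial torque is carried by the closed hand–bar coupling, which the
pure-force hand load cannot represent. The pronation coordinate carries no
muscle, and the scapulothoracic coordinates are kinematically prescribed.

**Infeasibility** is flagged, never silent: when no activation satisfies
balance and cone (about 3% of frames, concentrated at the 90°-abduction ×
1.5 BAW lockout where every bundle shares the same horizontal-plane torque
sign), the solver minimizes the balance violation under the remaining
constraints with a fixed effort weight of 1 N m per unit activation and
marks the frame; trials with >10% such frames carry a trial-level flag.

Joint reactions are quasi-static free-body balances: the GH reaction is
the force the humeral head exerts on the glenoid (external + gravity +
boundary-crossing muscle forces on the humerus+forearm body), the AC
reaction the force the scapula exerts on the clavicle. Decomposition uses
the glenoid basis (compression toward the glenoid center, anterior and
superior shear positive) and the clavicle basis (compression along the
clavicle toward the sternum). The decomposition is an exact isometry.

On a 10-subject cohort the emergent mechanics match expectation: wider
grips lengthen the external moment arms, demand more pectoralis force and
raise GH and AC compression through the loaded mid-cycle; abduction
effects concentrate at the cycle ends; a strongly medial hand force
inflates reactions. The mediolateral sweep (vertical share fixed at
78.48 N, fraction −0.5 to +2.0) shows minima of the mean reaction at
laterally directed forces, AC at a larger fraction than GH; the specific
minimizing fractions are properties of this reduced model and are not
asserted against any external value.

## 6. The statistical stage

Outcomes are resampled to the 101-point phase grid (51 descent + 51 ascent
nodes sharing the bottom). The first level fits, per subject and phase
node, OLS over the 27-column design (reference levels grip 1.5, 70°,
neutral — the middle conditions). Because the 21 performed cells never
combine the 1 BAW grip with 70°/90° abduction, 6 interaction columns are
aliased; `first_level()` errors by contract, and the pipeline passes
`drop_aliased = TRUE`, which removes them with an audit entry. A
consequence worth knowing: the `g1` main effect is then the narrow-grip
effect *at 45° abduction*.

The second level is a one-sample sign-flipping permutation t-test per term
across subjects, exhaustive when 2ⁿ ≤ 2¹⁴ and 10 000 sampled flips with a
mandatory seed otherwise. Family-wise control across the 101 nodes uses
the max-|t| distribution (node-level inference; random-field corrections
are out of scope); clusters are contiguous supra-threshold runs with
p-values from the same permutation distribution. Interaction tiers are
pruned top-down when fewer than 5% of their term×node results are
significant (the pruning rule is a config knob with audit logging, since
"only a few" is inherently vague); retained interactions trigger
stratified per-level analyses.

Calibration facts the test suite verifies: with 10 identical positive
continuums the exhaustive two-sided max-stat p is exactly 2/1024; under a
null simulation the family-wise error rate sits at α within binomial
error; a 3-SD effect confined to phase 40–60% is recovered there in ≥95%
of datasets. With n subjects the smallest achievable two-sided p is
2/2ⁿ — at n = 3 that is 0.25, so the 3-subject demo cannot show
significance at α = 0.05 by construction; effect-recovery checks run at
the protocol's cohort size of 10.

## 7. Problem sizes and numerical choices

The demo pipeline (3 subjects × 21 conditions × 2 repetitions) solves
kinematics and activations on an analysis grid of every 10th marker frame
(10 Hz), ample for 6 Hz-low-passed signals, and completes in about two
minutes; the 10-subject cohort takes about five. Other defaults:
Gauss–Newton tolerance 1e−9 with Levenberg damping; QP equality residual
accepted at 1e−6·(1+|M|); marker-gap limit 10 frames; repetition
prominence 0.05 m; 48 cone facets; exhaustive sign-flips up to 2¹⁴.
Degenerate inputs are contracts, not crashes: missing pulses, missing
calibration heights, unsafe conditions, rank-deficient designs and
zero-length muscle path segments all raise named errors; long gaps and
infeasible frames set flags.

## 8. Known limitations

Straight-line muscle paths (no wrapping) make axial moment arms and
extreme-posture geometry approximate; the scapulothoracic ellipsoid
contact is available as a concept but the default is measurement-driven
scapula kinematics; ligaments are absent; the infeasible-frame fallback
distorts continuums near lockout for the 90°-abduction × 1.5 BAW cells
(flagged); the synthetic cohort's between-subject variance is a single
propensity parameter rather than a full individual technique model; and
all statistical validation is performed on data generated under the
package's own assumptions.
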