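---
title: "Estimating lumbar moments with a reduced sensor set: models, synthetic data, and the calibration-set study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lumbar moments with a reduced sensor set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Actuated back-support exoskeletons should ideally deliver support
proportional to the moment the wearer's trunk muscles actively generate
about the lumbosacral (L5/S1) joint.  That moment cannot be measured
directly in the field.  The laboratory route — motion capture, force
plates, twelve surface EMG channels and an EMG-driven trunk muscle model —
is accurate but impractical to set up at a workplace.  This package
implements the practical alternative: a regression model that predicts the
active moment from only four back-muscle EMG channels plus five kinematic
signals an exoskeleton already measures, and — the part that decides
whether the approach is deployable — a systematic study of *how little
calibration data* suffices to train that regression without losing
accuracy.

Three models are chained:

1. **Inverse dynamics (ID)** — the reference.  A bottom-up Newton–Euler
   recursion from the measured ground reaction through feet, shanks,
   thighs and pelvis yields the net L5/S1 moment `M_net`.  With an
   exoskeleton worn, the human share is `M_human = M_net − M_exo`.
2. **EMG-driven muscle model (EMGMod)** — twelve Hill-type muscle
   elements (bilateral rectus abdominis, internal/external oblique,
   iliocostalis lumborum, longissimus thoracis pars lumborum and pars
   thoracis).  Element moments are
   `sign · G · a(t) · PCSA · f_l(λ) · f_v(λ̇) · r`, where `a(t)` is the
   MVC-normalized envelope, `r` the moment arm, and `λ` the normalized
   muscle length driven by lumbar flexion.  A passive extensor moment
   grows exponentially once the normalized length passes a slack offset.
   Seven subject-specific parameters are calibrated per person by
   minimizing `J = Σ_trials ∫ (M_human^ID − M_active(P) − M_passive(P))² dt`
   under box constraints.
3. **Regression model (RegMod)** — an epsilon-SVR with a coarse Gaussian
   kernel mapping nine features (4 EMG + trunk inclination, angular
   velocity, angular acceleration, trunk flexion, hip angle) to EMGMod's
   *active* moment.  RegMod never sees the ID moment: it is trained to
   imitate the calibrated muscle model, exactly as the deployment pipeline
   prescribes.

Accuracy of a calibration set is scored by the RMSE between the ID human
moment and each model's prediction (active + EMGMod passive) on held-out
test tasks, grouped into exoskeleton-assisted lifting, the lifting and
carrying phases of box stacking, shelf lifting, and isometric push/pull.

## Calibration sets

The calibration battery is the 14-condition ground-lift design: 2 masses
(7.5, 15 kg) × {stoop, squat} × {slow, normal}, plus 2 masses × free
technique × {very slow, normal, fast}, each condition performed twice.
From it the study builds:

* **Full** — all 14 conditions (the reference calibration);
* **Selected family** — every 3-condition subset covering both extremes
  of all three lifting characteristics: both masses, both technique
  extremes (stoop and squat), and both velocity extremes.  Because fast
  lifts exist only with the free technique, the velocity rule applies to
  the set as a whole: it must contain a very-slow-or-slow trial and a
  fast trial.  With the default battery the family has 18 members;
* **Worst-selected** — the family member with the largest across-subject
  mean RegMod RMSE over all test trials (ties broken by label);
* **Quasi-static** — only the two very-slow free lifts, the set that
  could be collected with minimal instrumentation;
* optionally, **every** subset of size 1–3 (14 + 91 + 364 evaluations per
  subject), behind the `sweep` flag of `run_study()`.

```{r}
library(exomoment)
res <- run_study(n_subjects = 10, seed = 1, sweep = TRUE)
print(res)
plot_task_rmse(res)
plot_sweep(res)
```

`run_study()` finishes with a two-way repeated-measures ANOVA
(calibration set × task group, subjects as the blocking factor, no
sphericity correction) and Bonferroni-adjusted pairwise comparisons,
implemented directly from the sums-of-squares decomposition and verified
against `aov()`'s error strata and a hand-computed fixture in the test
suite.

## The synthetic cohort

No public dataset carries this study's combination of signals, so the
package ships a first-class generator that emulates the experiment on a
planar (sagittal) five-segment chain — feet, shank, thigh, pelvis,
trunk+head, with arms hanging from the shoulder.  All study tasks are
sagittally symmetric, and every signal the downstream models consume is
sagittal, which is why the 3D marker-cluster model of the original
protocol collapses to this chain without losing anything the pipeline
uses.

* **Kinematics.**  Joint-angle tracks are minimum-jerk interpolations
  between posture keyframes (stoop: trunk to ~86° with knees nearly
  extended; squat: knees to ~110° with trunk below 35°; free: an
  intermediate mix).  Lifts are a lower–hold–lift cycle with the box in
  the hands throughout.  Velocity classes use per-phase durations of
  6 / 4 / 2.5 / 1.5 s (very slow → fast) — invented, configurable
  defaults; only their ordinal relation matters to the study.  Shelf
  lifts raise the load to ~1.5 m through an arm-elevation track; push
  and pull are static upright postures with a ±98.1 N (10 kg over a
  pulley) horizontal hand force ramped minimum-jerk; the stacking carry
  phase is modeled as a quasi-static upright hold with a small trunk
  sway, since gait is out of planar scope.
* **Ground reaction.**  Synthesized from the whole-body Newton–Euler
  balance of the same filtered trajectories, with the centre of pressure
  closing the moment equation exactly.  Bottom-up ID applied to these
  signals must therefore agree with the independent top-down moment over
  trunk + arms + load to numerical precision — the package's primary
  dynamics oracle (tested at < 0.5 N·m RMS, achieved at ~1e-13).
* **EMG.**  Generated by *inverting* the ground-truth muscle model: the
  required active moment (reference human moment minus the true passive
  moment) is divided over the agonist elements under an equal-drive
  synergy, antagonists sit at a 3 %-MVC co-contraction baseline whose
  moment is compensated inside the solve, and multiplicative log-normal
  noise (SD 0.05) is applied per channel with clipping to [0, 1.5].
  At zero noise the forward model at the true parameters reproduces the
  generated moment exactly, which is what makes calibration a
  parameter-recovery problem with a known optimum.
* **Exoskeleton.**  Support torque follows the control laws
  `τ = k₁α` (inclination), `+ k₂α̈` (dynamic), `+ k₃α̇` (velocity), or
  zero (transparent), with defaults k₁ = 30 N·m/rad, k₂ = 1 N·m·s²/rad,
  k₃ = 5 N·m·s/rad.  The forearm-EMG (hybrid) strategy is out of scope.
* **Cohort.**  Subject mass and stature are drawn around 73.8 kg /
  1.82 m (SD 7.6 kg / 0.09 m, truncated at ±1.5 SD); hidden muscle
  parameters are drawn per subject within documented sub-ranges of the
  calibration bounds (e.g. gain 50–90 N/cm², optimum angle
  0.45–0.75 rad).  Muscle PCSAs scale with body mass^(2/3) and moment
  arms with stature, so strength tracks body size.  Every trial's noise
  stream is seeded from (master seed, subject, trial id), making whole
  studies bit-reproducible.

What the generator deliberately does **not** emulate: model mismatch.
Real trunk muscles do not share one activation, electromechanical delay,
or the model's exact force–length/velocity shapes, so on real data EMGMod
carries an irreducible error (~20 N·m in comparable experiments) that
dominates total RMSE.  On synthetic data EMGMod is nearly exact
(~4–5 N·m at default noise), so the RegMod fitting error — and with it
the *relative* spread between calibration sets — is more visible here
than it would be on real recordings.  Passing the study's qualitative
checks therefore says the pipeline ranks calibration sets correctly, not
that its absolute RMSEs transfer to any particular laboratory dataset.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `gain` (G) | N/cm² per unit activation | bounds 10–120 | EMG-to-stress scaling; ~60 gives realistic maximal extensor moments (~160 N·m) for a 74 kg subject |
| `passive_offset` (λ₀) | – | bounds 0.9–1.3 | normalized length where passive tension starts |
| `passive_scale` (S_p) | N/cm² | bounds 0–60 | passive curve magnitude; shape constant c = 8 fixed |
| `ecc_scale`, `con_scale` | – | bounds 0–0.8, 0–1 | eccentric/concentric force–velocity scalings, saturating at a reference velocity of 1 s⁻¹ |
| `optimum_angle` | rad | bounds 0–1.2 | lumbar flexion at optimum muscle length |
| `fl_width` (w) | – | bounds 0.2–1.0 | Gaussian force–length width; implemented as the seventh calibratable parameter (the original description enumerates six; the width is the natural seventh and is flagged as a design choice) |

Muscle geometry (moment arms 0.045–0.08 m, PCSAs 4–20 cm², nominal fiber
lengths) ships as a documented in-code table (`muscle_geometry()`), all
values overridable.  Lumbar flexion — the thorax-relative-to-pelvis angle
— drives muscle length; trunk inclination would conflate hip motion with
lumbar strain.  Moments are reported extension-positive (the supporting
direction); flexion angles are positive.

## Numerical choices

* **Filtering.**  All Butterworth filters are applied zero-phase
  (forward–backward, odd-symmetric padding, steady-state initial
  conditions), matching standard offline practice and preserving the
  synchronization the pipeline depends on; a `zero_phase = FALSE` flag
  allows causal operation.  Markers/forces: 2nd order, 5 Hz.  EMG chain:
  band-pass 10–400 Hz, high-pass 30 Hz (ECG suppression), rectify,
  low-pass 2.5 Hz, MVC-normalize; an optional mains notch is off by
  default.  Resampling to 50 Hz uses an anti-alias low-pass at 20 Hz
  before decimation, with no net group delay.
* **Differentiation.**  Central differences (one-sided at the ends) on
  5 Hz low-passed angles; accelerations by double application.
* **Calibration.**  The objective is the rectangle-rule discretization of
  the squared-error integral at Δt = 0.02 s, trials concatenated with
  equal weight.  Minimization uses box-constrained L-BFGS-B with an
  analytic gradient (verified against finite differences), started from
  the bound midpoint plus seeded Latin-hypercube points (5 starts by
  default); best objective wins, ties broken by lower gain.  The
  interior-point method of the original toolchain and projected
  quasi-Newton solve the same smooth box-constrained problem; L-BFGS-B is
  the standard R equivalent.
* **SVR preset.**  "Coarse Gaussian" is reproduced by its documented
  convention: z-scored features, kernel scale `4·√9` (γ = 1/288), box
  constraint `IQR(y)/1.349`, epsilon tube `IQR(y)/13.49`.  The epsilon
  tube sets the resolution floor of the fit: residuals inside it are
  unpenalized, so CV RMSE cannot fall much below `IQR/13.49` however
  clean the target.  Cross-validation folds are contiguous blocks by
  trial, because 50 Hz samples are strongly serially correlated and
  random-row folds would leak.  Training sets are thinned to a uniform
  stride above a row budget (default 2000 rows; envelopes and kinematics
  are heavily oversampled at 50 Hz relative to their 2.5 Hz bandwidth).
* **Degenerate inputs.**  A response entirely inside the epsilon tube
  yields no support vectors; prediction then falls back to the response
  mean.  Constant signals are rejected by the delay estimator; a
  non-uniform time base, a missing channel, an unbalanced ANOVA design,
  or an empty calibration set raise named errors.
* **Problem sizes.**  The shipped study scale — 10 subjects for the
  set evaluation, 20 for parameter recovery, the full 469-subset sweep
  with a reduced optimizer budget (2 starts, stride 3, 700-row SVR
  budget) — was chosen so a complete run takes minutes on one core while
  leaving every qualitative contrast far from its decision boundary.

## Known limitations

* Planar sagittal mechanics only; asymmetric lifting, gait, and
  frontal/transverse moments are out of scope.
* The L5/S1 joint sits at a fixed fraction of pelvis height above the
  hip; the original landmark-based estimate is not reproducible without
  marker data.
* The carry phase of stacking is a quasi-static hold, not walking.
* EMGMod calibration is near-exact on synthetic data (see above), so
  absolute RMSEs are smaller, and relative spreads between calibration
  sets larger, than on real recordings.  In our runs the worst Selected
  member sits ~27 % above the Full set where the real-data study found
  ~13 %; the ordering of sets, the degradation of the Quasi-static set
  on dynamic lifting, and the monotone improvement of the best subset
  with set size all reproduce.
* MVC normalization is modeled as given peak values; the exertion
  protocol itself is not simulated, and raw synthetic EMG carriers are
  only used to exercise the envelope chain, not to model
  electrophysiology.
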