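---
title: "Head-trunk coordination in auditory virtual reality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head-trunk coordination in auditory virtual reality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Goal-directed reorientation in the horizontal plane normally relies on an
*articulated* strategy: the head turns first and largely independently, and
the trunk follows in a loosely coupled way. Young children instead move head
and trunk *en bloc*, as a single rigid unit, and there is evidence that
people who lost vision early keep an en-bloc-like coupling into adulthood.
`headtrunk` packages a complete, testable version of an experimental
paradigm for probing that question with auditory-only virtual reality: a
seated participant steers a virtual "arrow" toward a sound source using head
yaw alone (*free* coordination) or head-minus-trunk yaw (*forced*
coordination, which implicitly and explicitly demands trunk immobilization),
with the target either straight ahead (*central*) or 15° to the side
(*lateral*). The package provides

1. a deterministic simulator of the steering task (`avr_task` layer);
2. a synthetic-cohort generator whose agents reproduce the hypothesized
   group structure (en-bloc vs articulated coupling, trunk "damping");
3. the kinematic measure pipeline (trunk jerk RMS and the prewhitened
   head-trunk jerk cross-correlation peak);
4. spatial-performance measures (accuracy = median signed final error,
   precision = its interquartile range, with a Lilliefors normality screen);
5. the rank-based inferential layer (aligned-rank-transform mixed ANOVA,
   exact Mann-Whitney / Wilcoxon post-hocs, rank-biserial effect sizes).

Everything downstream of the simulator also accepts real data: an imported
long table of participant × condition measures drops straight into the same
ANOVA and post-hoc functions.

## The task model

The virtual playfield is a horizontal metric plane. The arrow is loaded at
the origin; the target is a pink-noise source 60 m away at azimuth −15°, 0°
or +15° (positive = rightward). Trigger-window and target centers are always
15° apart, so *central* trials start the arrow 15° to the side and *lateral*
trials start it straight ahead. A trial has two steps:

* **positioning** — the arrow only rotates; once its orientation has stayed
  inside the trigger window continuously for a dwell time drawn uniformly
  from 1–3 s, the shot fires. An intermittent pure tone whose pitch rises as
  the arrow approaches the window (exponential map, 220–880 Hz over 0–180°)
  stands in for the experiment's acoustic positioning feedback; audio is
  modeled only as these mappings, never rendered.
* **execution** — the arrow advances at 10 m/s along the heading commanded
  each tick; under free coordination the heading is the head yaw, under
  forced coordination it is head minus trunk yaw.

Choices the task description leaves open, fixed here once:

* **Termination.** The trial ends when the cumulative path length reaches
  the 60 m target distance (the last tick is truncated so it lands exactly
  there). This makes the execution step exactly 6 s at 10 m/s regardless of
  trajectory shape, and is side-neutral. A hit is an endpoint within 1 m of
  the target center (configurable).
* **Clock.** Integration and sampling share one 90 Hz clock. The original
  platform ran physics at 30 Hz under a 90 Hz main loop; collapsing the two
  removes an interpolation layer that is irrelevant to the measures.
* **Trigger half-width.** 2.5° by default; anything below 15° keeps window
  and target disjoint.
* **Positioning timeout.** 30 s, after which the trial is flagged invalid
  and reported (never silently dropped). The human protocol has no failure
  path; a simulation needs one.
* **Signed error.** The line from the origin through the target center
  splits the plane into two hemispaces; the final error magnitude is the
  endpoint-to-target Euclidean distance, and the sign is positive when the
  endpoint lies in the hemispace of the initial arrow trajectory. The
  source description of this convention is internally contradictory (its
  results prose implies the opposite polarity), so `signed_final_error()`
  exposes a `sign_convention` switch; the operational definition above is
  the default.

## The synthetic agents

Humans are not modeled biomechanically. Each agent is the simplest
controller family that produces smooth, jerk-analyzable yaw and the group
statistical structure the analysis needs:

* **Head**: the steering error (goal azimuth minus arrow heading), observed
  with a 150 ms reaction delay, is converted to a velocity command with
  proportional gain 3 s⁻¹, smoothed by two cascaded first-order low-pass
  stages (τ = 120 ms each, a second-order response), integrated, and
  perturbed by white motor noise of 0.2° per tick.
* **Trunk**: mirrors a fraction κ (`coupling_kappa`) of every head
  increment; under forced coordination that fraction is further multiplied
  by γ (`damping_gamma`), the "damping" behavior of reducing trunk
  amplitude rather than suppressing trunk motion. Independent trunk tremor
  is 0.25 × the head motor noise — smaller because the trunk is far more
  massive; the factor is a fixed design constant, chosen so the trunk
  channel is signal- rather than tremor-dominated at moderate coupling.

Group distributions (truncated normal on [0, 1]) encode the hypothesized
contrast: blind κ ~ N(0.85, 0.1) with γ ~ N(0.3, 0.1) (strong coupling,
strong voluntary damping when demanded), sighted κ ~ N(0.15, 0.1) with
γ = 1 (weak coupling, no condition-dependent change). Cohort layout matches
the study: 10 blind, 11 sighted, 20 trials per condition, side randomly
alternated between leftward and rightward.

The acquisition chain is emulated by `degrade_sensors()`: Gaussian
timestamp jitter (2 ms SD, standing in for asynchronous UDP collection),
2% sample dropout, slow linear drift on the trunk channel (0.05°/s,
IMU-like, reset every 10 trials as recalibration), and quantization of both
channels to the 0.1° sensor resolution.

What the generator does **not** emulate: torque/inertia dynamics, vestibular
feedback, learning across trials, head-on-trunk range limits, or any
quantitative kinematic magnitudes (no peak-velocity data exist to calibrate
against). Passing end-to-end tests therefore show that the *analysis
pipeline* discriminates the programmed group structure — not that real
blind and sighted kinematics look like these agents.

Reproducibility: one master seed; each (participant, condition, trial)
stream gets a sub-seed from a multiplicative-congruential hash
(`derive_seed()`), so any single trial can be regenerated in isolation.

## The kinematic measures

Per trial, both yaw channels go through the same chain:

1. **Resample** at 90 Hz by linear interpolation over the observed time
   range (compensates jitter and dropout; no extrapolation).
2. **Smooth** with an 18-sample moving average. An even window has no
   integer center; the output is aligned 9 samples left / 8 right, and the
   induced half-sample delay is identical for both channels, so relative
   head-trunk timing is untouched. Only full windows are kept.
3. **Jerk**: three successive central differences (exact on cubics — the
   basis of its unit tests); three boundary samples are lost per side.
4. **Trunk jerk RMS** — how much the trunk moved. Computed on the smoothed
   jerk, since smoothing precedes all further analysis.
5. **Prewhitening**: kinematic samples are strongly autocorrelated, which
   inflates cross-correlation. An AR(p) model is fitted to the head jerk
   series by OLS with AIC order selection (max order 20, stationarity
   asserted), and *both* series are passed through the same innovation
   filter — identical filtering preserves relative lag. Fitting on the
   trunk, or each series on itself, are available options
   (`fit_on = "trunk"` / `"each"`).
6. **Cross-peak**: the maximum of |r| of the normalized cross-correlation
   over lags within ±0.5 s (physiological head-trunk lags are sub-second;
   window configurable), ties resolved toward zero lag. The
   absolute-value convention captures anti-phase coupling; a signed option
   exists.

Degenerate trials (zero-variance trunk jerk, e.g. a perfectly immobile
trunk) get `trunk_rms = 0` and a *missing* cross-peak — imputing 0 would
claim "dissimilar", which is wrong for an immobile trunk. Exclusions are
counted and reported by `aggregate_participant()`, which collapses trials
to participant × condition medians.

## Performance measures and the normality screen

Accuracy is the median signed final error; precision is the interquartile
range under the linear-interpolation quantile convention (type 7 — the
convention is stated because the source does not name one). The Lilliefors
test (sup distance between the ECDF and a normal CDF with estimated
moments) uses a seeded Monte-Carlo null (default 10,000 replicates) rather
than critical-value tables; the statistic is affine-invariant, so simulating
standard normals is exact up to Monte-Carlo error.

## The inferential layer

All four measures are analyzed with a 2 × 2 × 2 mixed-design ANOVA on
aligned-rank-transformed data: group (between) × direction × coordination
(within). For each of the seven effects the response is aligned — full
factorial cell mean removed, the target effect's own estimate (unweighted
cell-mean inclusion-exclusion) added back — then midranked over the whole
sample, and a standard mixed ANOVA on the ranks is read out at that
effect's own error stratum: group against participants-within-group
(df₂ = n − 2 = 19 for 21 participants), within effects against their
participant-interaction strata. Alignment correctness is tested by the
standard stripping diagnostic (all other effects' F ≈ 0 on aligned data)
and by a 500-replicate null calibration of the per-effect type-I rate.

Post-hoc comparisons between interaction levels sharing one main level use
the exact Mann-Whitney test between groups and the exact Wilcoxon
signed-rank test within groups. Exactness is authored, not approximated:
the U null distribution comes from the lattice-path count recursion, the W
null from the subset-sum convolution; both are verified against full
enumeration (all group labelings / all 2ⁿ sign patterns) and against the
base R distribution functions. Ties fall back to midrank normal
approximations with tie correction (continuous measures make ties
measure-zero here). P-values default to two-sided — the published
statistics are numerically consistent with two-sided exactness even where
directional hypotheses were stated — with `alternative` switches; the
end-to-end replication check uses the directional alternatives that the
original post-hoc hypotheses specify. Bonferroni m is the number of
comparisons within one interaction suite (4 for a two-way interaction, 12
for the three-way cube). Factors not named in the interaction are collapsed
within participant by the median before testing (the collapsing rule is
not stated in the source; pooling is the alternative we rejected as it
mixes within-cell variances).

Effect sizes: partial eta squared for ANOVA rows
(F·df₁/(F·df₁ + df₂)); rank-biserial correlation for post-hocs
(r = 2U/(n₁n₂) − 1, or (2W − T)/T with T = n(n+1)/2), with percentile
bootstrap confidence intervals (participants resampled within group, or
pairs for within-group contrasts; 10,000 replicates, seeded, clipped to
[−1, 1]) — the source does not state its interval method.

## Problem sizes and numerical choices

The default cohort (21 participants × 4 conditions × 20 trials, ~540
execution samples per trial) runs the full pipeline in about a minute on
one core; the test suite uses this size once for the end-to-end pattern
check and smaller cohorts (4 + 4 participants, 3 trials) elsewhere. The
ART null calibration uses 500 replicates of the full 21-participant
design; coupling-recovery properties use 20 agents per κ point and 30
agents for the Spearman check, 2 trials each. Exact-test oracles enumerate
completely (n ≤ 10 sign patterns, n₁ + n₂ ≤ 12 labelings). Bootstrap
intervals in the analysis scripts use 10,000 replicates; in-test intervals
use 500 to keep the suite fast.

Degenerate inputs are errors, not silent values: empty histories,
non-increasing timestamps, zero-variance series for prewhitening or
cross-correlation, all-zero difference vectors, missing design cells (the
offending participant and cell are named). Positioning timeouts mark the
trial invalid and propagate as a reported count.

## Known limitations

* The agents are control-theoretic stand-ins; only the relational
  structure (coupling, damping, noise) is meaningful, not kinematic
  magnitudes. Absolute trunk-RMS values are in deg·s⁻³ of the synthetic
  controller, not of human movement.
* The prewhitening methodology of the original analysis lives in an
  unavailable supplement; the Box-Jenkins choice here (AR on the head
  series, AIC order, shared filter) is standard practice but not verified
  against the original.
* The ART alignment uses unweighted cell means; with the unbalanced 10/11
  groups the stripping diagnostic is satisfied only to numerical noise
  (F < 0.01), which is expected for this estimator.
* With few participants the bootstrap interval for rank-biserial r is
  wide and its coverage approximate, especially at complete separation
  (where it clips at ±1).
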