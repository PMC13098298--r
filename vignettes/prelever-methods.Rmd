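---
title: "From pose tracks to incentive-salience phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pose tracks to incentive-salience phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prelever` turns two raw inputs — per-frame pose-estimation tables from an
overhead camera and operant event logs from a self-administration rig —
into the behavioral markers used to study how addiction-like cocaine
seeking develops in rats: locomotion, nose motion, lever-zone entrances per
meter, loading-window intake, progressive-ratio breakpoints, and two
subject-level phenotypes (psychomotor sensitization vs. tolerance, and
high vs. low incentive salience). This vignette documents the models,
conventions, and numerical choices behind each stage, and what the
synthetic cohort generator does and does not emulate.

```{r setup}
library(prelever)
```

## The measurement pipeline

### Pose tables and interpolation

A recording is a `pose_track`: one row per frame at a fixed frame rate
(default 10 frames/s), with `(x, y)` pixel coordinates for 13 tracked
nodes (nose, ears, neck, four paws, tail base, the catheter implant used
as the body anchor, both levers, and the active-lever cue light). Pixel
origin is top-left with y increasing downward; frame indices are 0-based
and made gap-free on ingestion. Pose-estimation output has dropped frames
and failed detections, so missing coordinates are filled per node by
linear interpolation between the nearest observed frames, with leading and
trailing gaps taking the nearest observed value. Linear filling is the
convention of the pose-estimation tooling this format emulates; observed
frames are never altered, and a node with no observations at all is a
hard error rather than a silent zero.

### Calibration

An overhead fisheye lens distorts the chamber image, so a single ruler
measurement is biased. The cm/px factor is instead the mean of five
ratios: two length and three width (top, middle, bottom) measurements of
the chamber grid against its known physical dimensions
(`compute_cm_per_px()`). The default geometry uses 0.111 cm/px for a
30 x 25 cm floor imaged as 270 x 225 px.

### Alignment to lever extension

Every session is recorded for 30 min and, in self-administration
sessions, the levers extend after 15 min. Recordings are trimmed to
exactly 12.5 min of frames on each side of the extension so all sessions
contribute segments of identical length; the pre-lever segment is the
anticipatory window on which the incentive-salience metrics are computed.
Noncontingent recordings (no levers) are trimmed symmetrically to 25 min.
A recording whose extension sits too close to an edge cannot supply both
segments; it becomes a reason-coded exclusion, never a silent drop, and
the pipeline reconciles recording counts against the exclusion audit.

### Locomotion and nose motion

Path length is the sum of frame-to-frame Euclidean displacements of a
node, converted to meters. Coordinates are first smoothed by a centered
moving average of 10 frames; the smoothing target is deliberately the
*coordinates*, not the per-frame displacement series, because averaging
positions suppresses sub-pixel tracking jitter before it is rectified
into spurious distance by the differencing step. (Smoothing the
displacement series instead is exposed via `smooth = "displacements"`.)
The moving-average window shrinks symmetrically at the edges so the
output keeps its length; any averaging window can only reduce total
variation, so smoothed path length is never larger than the raw one.
Locomotion is measured on the catheter node (a stable body anchor on the
back); nose motion on the nose node. The frame rate and the smoothing
window are independent configuration knobs on purpose — no relation
between them is assumed.

### Lever zones and entrances per meter

Each lever defines a rectangular region of interest of ±30 px in x and
±18 px in y around the lever node. Because levers are physically fixed,
the zone is anchored at the per-session *median* of the tracked lever
coordinates — robust to tracking flicker, and immune to the ROI jitter
that per-frame anchoring would cause. Membership is half-open
(`lower <= p < upper`) so a point on a shared edge belongs to exactly one
zone. An entrance is an outside-to-inside transition of the nose; a track
that starts inside contributes no entrance until it exits and re-enters.
No minimum-dwell debounce is applied by default (`min_dwell_frames`
exists for robustness studies). Entrances are normalized by locomotion
over the same frames — entrances per meter — separating directed seeking
from general hyperactivity. Below a locomotion floor (0.01 m) the ratio
is undefined and propagates as `NA` with a reason code, not as 0 or
infinity. Interpolation precedes entrance detection, so missing nose
frames inside a zone count toward dwell; this module ordering is a
documented convention.

### Session scalars

* `first15_infusions()` counts infusions in the half-open 15-min window
  after lever extension — the loading window where intake is maximal and
  whose length matches the pre-lever observation window. Anchoring at
  recording start instead is a configuration option.
* `abstinence_code()` snaps inter-session gaps to 18 h (consecutive
  weekdays), 66 h (two-day weekend) or 90 h (three-day weekend). The
  ±6 h tolerance absorbs calendar jitter (sessions of different lengths
  end at different times) while keeping the bands disjoint; a gap outside
  every band is a schedule anomaly and errors.
* `pr_requirement(n)` is the exponential progressive-ratio schedule
  `5·exp(0.2·n) − 5`, rounded half-away-from-zero and floored at one
  press (the classic integer schedule this formula reproduces);
  `pr_breakpoint()` returns the last requirement completed before the
  first 60-min span without a completion, 0 if nothing was completed.

## The two phenotypes

**Sensitization vs. tolerance.** Each subject receives three identical
noncontingent drug challenges across the study. A subject whose
locomotor response increased from the first to the third challenge is
labelled *Sensitization*; decreased, *Tolerance*. An exact tie is
*indeterminate* and excluded with a reason code rather than forced onto a
side — the dichotomy need not cover every subject.

**High vs. low incentive salience.** Pre-lever locomotion and pre-lever
active-lever entrances per meter are averaged per subject over Short
Access sessions 07–09 (the last three Short Access sessions of a single
week, hence no abstinence gaps between them), each variable is
z-standardized across the cohort (n−1 denominator), and the two z-scores
are averaged. Subjects at or above the cohort median are "high", below
it "low"; with an odd number of distinct scores the ≥-median rule forces
an (n+1)/2 vs. (n−1)/2 split — 19 vs. 18 in a 37-subject cohort. When a
subject misses one of the three sessions the average uses the sessions
available. The split is invariant under any strictly increasing
transform of the score.

## The statistical workflow

Behavioral metrics are nonnegative and right-skewed, so outliers are
winsorized at the 95th percentile — upper tail only; a symmetric variant
is exposed but not the default. The cap is the type-1 (inverse-ECDF)
empirical percentile, an observed value, which makes winsorization
idempotent. Responses that need it are power-transformed: Box-Cox for
strictly positive variables, Yeo-Johnson otherwise, with lambda chosen by
maximizing the standard profile log-likelihood over a grid on [−2, 2] in
steps of 0.01 plus local refinement. Correlations are normality-gated:
Shapiro-Wilk on each variable, Pearson only if both are compatible with
normality at α = 0.05 (the gate level is configurable; 0.05 is an
assumption, not an external requirement), Spearman's rank otherwise.
Families of p-values are adjusted by the Benjamini–Yekutieli step-up,
which controls the false-discovery rate under the arbitrary dependence
typical of repeated measures from the same animals; it is implemented
from its defining formula and is always at least as conservative as
Benjamini–Hochberg.

Mixed-model estimation itself is deliberately delegated:
`run_model_suite()` prepares responses (winsorize, then transform, in
that order), hands linear mixed models to `lmerTest` (Type III F tests,
Satterthwaite degrees of freedom) and generalized ones to `glmmTMB` with
Type III Wald chi-square tests, pools the raw p-values through the BY
adjustment, and records the full pre-processing provenance (caps,
transform family, lambda) with every fit. Re-deriving REML or
Satterthwaite machinery is out of scope; when no backend is installed
the suite degrades to per-subject summaries with a warning.

## The synthetic cohort generator

No public recordings accompany the study design this package analyzes,
so the generator produces cohorts with the statistical structure the
analysis assumes, plus the ground truth needed for parameter-recovery
tests.

**Trajectory model.** The body anchor follows a discrete-time
mean-reverting (Ornstein–Uhlenbeck-style) velocity process with
reflecting chamber walls: the simplest process with tunable mean speed,
momentum, and a zone-directed bias. Velocity noise is calibrated so the
stationary mean speed equals the subject's `baseline_speed` (default
population: log-normal around 3 cm/s). Attraction toward the
active-lever zone enters as a constant-magnitude pull proportional to
the subject's `salience_weight`, scaled by the subject's own speed (a
motionless subject feels no pull) and softened within 30 px of the
target to avoid oscillation. The nose wanders around the anchor with
its own smooth zero-mean jitter; body nodes ride on rigid offsets plus
tracking noise; lever and cue-light nodes are static up to sub-pixel
noise with rare large flicker (which the median zone anchor must
absorb). All coordinates are folded back into the chamber by
reflection — reflection, unlike clamping, preserves a uniform occupancy
density, which is what makes the zero-salience occupancy calibration
(zone occupancy ≈ zone area / chamber area for an interior zone)
testable. Walk parameters (velocity autocorrelation 0.9, attraction gain
0.05, nose spread 10 px with autocorrelation 0.99) were chosen so that a
typical subject produces noncontingent-session entrance counts of the
observed order of magnitude (tens per 25-min recording, near-equal
between levers at baseline attraction, roughly doubled toward the active
lever after repeated drug exposure) — the generator is a study-structure
emulator, not a fitted movement model.

**Behavioral state.** During the pre-lever segment of
self-administration sessions, salience also raises locomotor speed
(anticipatory hyperactivity, gain 0.15 per unit weight) — this is what
couples the two incentive-salience variables the way the analysis
expects. After lever extension a fixed drug-on-board multiplier (1.6)
applies. In noncontingent sessions the Drug phase multiplies speed by
`drug_effect × slope^(k−1)`: a first-challenge response of 2× baseline,
then geometric growth or decay by the subject's `sensitization_slope`
(population default centered slightly below 1, so tolerance outnumbers
sensitization as observed in heterogeneous stock rats). Zone attraction
in noncontingent sessions scales with challenge number (gains 0.2, 0.5,
1.0) so preferential seeking of the active-lever area emerges by the
third challenge.

**Event logs.** Fixed-ratio sessions draw infusion onsets from a rate
process with a 3× rate in the first 15 min after lever extension (the
study design states loading exists but no magnitude; 3× is a documented
default), a per-session additive escalation trend, and a hard 26-s
refractory period (6-s infusion + 20-s timeout). Shock sessions flag
each infusion independently with probability 0.30. Progressive-ratio
sessions simulate ratio completions at a subject-specific press rate and
end at the first 60-min lapse. Noncontingent phases carry one
experimenter-delivered infusion at time zero — saline, or 1.5 mg/kg of
drug, three times the 0.5 mg/kg self-administration unit dose.

**Calendar.** The default schedule runs Monday–Friday: a noncontingent
triplet (Baseline/Saline/Drug, three 30-min recordings) before the first
Short Access session, 10 two-hour Short Access sessions with the second
noncontingent session after Short Access 09, 15 six-hour Long Access
sessions (with one holiday Monday so a 90-h gap occurs naturally), a
third noncontingent session, three progressive-ratio sessions, then
Preshock and Shock. That is 30 self-administration sessions per subject;
a 37-subject cohort therefore emits exactly 1110 self-administration and
333 noncontingent recordings. Sessions start at 08:00, which lands every
inter-session gap inside the 18/66/90 ± 6 h bands.

**Missingness.** Each node independently loses 2% of frames plus
occasional multi-frame gaps (about one per 15 min, geometric lengths),
exercising the interpolation stage. The rate is configurable;
`missing_rate = 0` produces complete tracks.

**What the generator does not emulate.** Pharmacokinetics, stereotypy
(nose motion exists as a metric but no pathological nose-motion regime
is simulated), sex differences (sex is carried as a label only, 21:16
male:female by default), posture and body orientation, video artifacts
beyond coordinate flicker, and any quantitative escalation magnitude —
escalation rates are free parameters, not calibrated to a real cohort.
Passing recovery tests therefore shows the pipeline correctly inverts
*this* generative structure, not that it would recover phenotypes from
any real video.

## Design decisions and degenerate inputs

* Ambiguous smoothing description ("distances smoothed by a window")
  resolved as coordinate smoothing, with the displacement variant
  exposed; documented above.
* The intake window is anchored at lever extension (not recording
  start); both offsets are available because the convention is implied
  rather than stated in the protocols this mirrors.
* Bimodal populations for recovery studies use balanced component
  assignment (exactly half the cohort per mode, order randomized), so a
  median split compares like-sized groups and concordance measures
  separation rather than binomial imbalance.
* Ties: an exact sensitization tie is indeterminate; identical z-scores
  all classify "high" under the ≥-median rule; a constant variable makes
  the z-score error out (zero variance).
* Degenerate inputs error loudly and early: empty pose tables, missing
  required nodes, zones outside the chamber, non-positive calibration
  measurements, p-values outside [0, 1], Box-Cox on non-positive data
  (with a pointer to Yeo-Johnson).
* Determinism: every stochastic stage takes or derives an explicit seed;
  a cohort simulated twice with the same seed is bit-identical, and the
  pipeline's output tables are byte-identical across reruns.

## Problem sizes used in the test suite

The suite simulates the full 37-subject bookkeeping run (1443
recordings, counted in a streaming sink), parameter-recovery cohorts of
16 subjects over the five informative sessions for 20 seeds, 10^4-plus
shock-session infusions, 10^4-sample transform-recovery draws, and 1000
random instances per brute-force oracle comparison. These sizes were
chosen as the smallest that make the stochastic checks statistically
decisive (3-sigma envelopes) while keeping a full run comfortable on a
single CPU.

## Known limitations

* The cm/px factor of a real rig must come from grid measurements; the
  default is a plausible constant, not a calibration of any camera.
* The HDF5 pose dialect of some pose-estimation exporters is not read;
  the delimited dialect is the interchange format.
* `shapiro.test()` limits the normality gate to 5000 pairs; larger
  correlation problems need a different gate.
* Mixed-model results are only as good as the delegated backends; the
  package adds provenance and adjustment around them, not new
  estimators.
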