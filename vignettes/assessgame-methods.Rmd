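---
title: "Measuring selective voluntary motor control with a tracking game: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selective voluntary motor control with a tracking game: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assessgame)
```

## The measurement problem

Selective voluntary motor control (SVMC) — the ability to move one joint
without involuntarily moving others — is a core impairment in children
with spastic cerebral palsy. Clinical instruments such as SCALE grade it
on coarse ordinal scales; this package implements an interval-scaled
alternative built around a tracking game. The child steers an avatar
vertically on a screen using flexion/extension of a single target joint
(hip, knee or ankle), while six pairs of 3-axis accelerometers — one
proximal (reference) and one distal sensor per joint, bilaterally —
record what every joint actually did.

Each trial consists of a 25 s accommodation phase followed by a 30 s test
phase in which the avatar must follow a smooth star-studded path of
upward and downward curves. Two outcomes are computed offline per trial:

* **Accuracy score** — the RMSE between avatar and target path over the
  test phase, divided by the SD of the same error in a cohort of
  neurologically intact adults ("movement mastery"). Units: adult SDs;
  0 is a perfect trace; larger is worse.
* **Involuntary movement score (IMS)** — for the five non-target joints,
  the mean absolute angular speed over the test phase is compared with
  the adult mean and scaled by the adult SD; the IMS is the average of
  these five standardized excesses. 0 means adult-like stillness;
  larger is worse. The IMS is not clipped, so slightly negative values
  (stiller than the average adult) occur.

Per-joint scores are summarized as means over the more-affected leg, the
less-affected leg (side labels come from the clinical diagnosis, never
from the scores), and all testable joints.

## From acceleration to joint angle

Game movements are slow and seated, so each accelerometer is treated as
a quasi-static gravity sensor. Channels are low-pass filtered with a
4th-order Butterworth at 1.5 Hz, applied forward and backward
(zero-phase); the sagittal inclination of a sensor is
`atan2(a_x, -a_z)` in degrees, and the joint angle is distal minus
proximal inclination. The difference construction means whole-segment
compensatory motion — which tilts both sensors together — cancels
exactly, and any common inclination bias drops out. Angular speed is the
forward first difference times the sampling rate, with the last value
repeated to preserve length. Samples where the filtered total
acceleration stays below 0.3 g are flagged as unreliable for
inclination.

The cutoff trades bias against noise, and the choice is driven by the
*speed* channel: differentiation amplifies whatever high-frequency
noise the filter passes, so white sensor noise of SD 0.02 g leaves a
speed-noise floor of several deg/s at a 3 Hz bandwidth — enough to mask
the small involuntary movements the IMS exists to detect (a small
coupled movement then enters the mean-absolute-speed metric only
quadratically). The target paths contain no energy above ~0.35 Hz and
seated single-joint movements live well below 1 Hz, so a 1.5 Hz cutoff
passes all task-band movement while reducing the noise floor roughly
threefold. Because the reference adults are measured with the same
chain, whatever floor remains cancels in the standardized scores.

### Missing samples

Occasional single-sensor dropouts are imputed before angle estimation:
each missing sample is predicted by a local regression on a ±0.5 s
window of the same channel (linear trend in time) plus the synchronous
channels of the other sensor of the same joint, and the mean of 50
residual-noise draws is imputed. The draw-averaging mirrors multiple
imputation by chained equations at the scale of short sensor gaps; for
the sub-1% gap rates the hardware produces, imputed channels correlate
>0.99 with ground truth (see the test suite). A joint with ≥ 20% of
samples missing in either sensor is flagged untestable and excluded from
scoring — the same rule that excludes joints with an active ROM below
10°, and exclusions propagate to the comparator analyses.

## Calibration and the target path

The game is calibrated to the participant's maximum active ROM; play
uses the central 90% of it, mapped affinely to screen positions 0–1 with
a symmetric 5% margin at each end (where the margin sits is not dictated
by the measurement concept; centring is the simplest choice). Angles
outside clamp to the screen edges. ROMs below 10° are rejected as
untestable.

Target paths are random-phase sums of 2–4 sinusoids with periods of
3–10 s, rescaled into [0.05, 0.95] so the child never has to pin the
screen edge; any smooth curve with both upward and downward segments
satisfies the design. Paths are deterministic per seed and each trial's
seed is recorded in the session file.

## The synthetic cohort generator

No recordings are distributable, so the package ships a simulator that
generates the full study design: 31 neurologically intact adults (the
reference cohort, ages 18–50), 31 neurologically intact children
(controls, ages 6–18), and 20 children with CP (patients, ages 8–17.5),
each playing all six target joints, patients twice (test and retest).
Every participant carries latent parameters retained alongside the data,
which is what makes parameter-recovery testing possible.

The generative model per trial:

* the avatar is the target path delayed by the participant's visuomotor
  lag (uniform 0.01–0.08 s) plus smoothed Gaussian tracking noise of SD
  `sigma_track` (screen units), clipped to the screen;
* the target-joint angle is the inverse screen map of the avatar;
* each non-target joint moves with its coupling gain `c_j` times the
  *intended* (path-following) excursion — involuntary coupling mirrors
  the voluntary drive, not the tracking error — at full weight for the
  contralateral homologue (mirror movement), weight 0.6 for ipsilateral
  adjacent joints and 0.3 otherwise, plus band-limited resting fidget
  noise (angular-speed SD 1 deg/s);
* angles become accelerometer readings through a pure-gravity sensor
  model (proximal sensor static, distal inclined by the joint angle)
  with white noise of SD 0.02 g, and samples are dropped in short
  bursts at a 0.8% rate;
* the trunk is *not* simulated as a seventh sensor pair (matching the
  hardware); a latent trunk variable drives only the simulated
  therapist's rating.

Group structure: control children's coupling gains and tracking noise
decay log-linearly with age toward adult levels (maturation of selective
control, rate 0.16/year); patients carry a per-person log-normal
severity factor that multiplies all coupling gains (and, with exponent
1/2, tracking noise), plus a 1.5× factor on the more-affected side.
Adults' tracking skill is deliberately heterogeneous (log-SD 0.75):
the adult SD is the denominator of the accuracy score, and only a
reference cohort with substantial spread places typical patients in the
score range a heterogeneous clinical cohort occupies (medians ≈ 2.5 for
accuracy and ≈ 1.6 for the IMS, ranges ≈ 1–6). Between-person spread of the resting
fidget level is kept small (log-SD 0.03): the adult SD of a movement
cell then reflects trial-to-trial measurement variability, which
averages out across a child's thirty non-target cells. If instead the
adult SD were dominated by stable person-to-person fidget differences,
every child would carry roughly one adult-SD of coupling-independent
IMS offset by construction, and no analysis could separate involuntary
coupling from restlessness. Those group medians and
the rating thresholds below were chosen once so that simulated cohorts
land inside the descriptive ranges reported for the instrument, not to
reproduce any specific cohort statistic.

Synthetic comparator ratings are thresholded, noisy views of the latent
impairment: SCALE per joint (2/1/0 for normal/impaired/unable) from the
joint's coupling gain after a person-level log-normal rating bias shared
across items plus item noise; GMFCS (I–V) from the mean coupling gain
after independent rating noise; the therapist's involuntary-movement
count (0–3, one point each for mirror, other-joint and trunk movements
observed at least once) from per-trial jittered drivers. The rating
noise is deliberate: clinical scales measure related but distinct
constructs (strength, gross function, task context), and the study found
only negligible-to-low agreement between the game scores and SCALE/GMFCS
but moderate agreement with the therapist's direct observation of the
game — the generator reproduces that ordering structurally, not by
fitting.

On retest, `sigma_track` and the coupling gains are perturbed by a
log-normal factor (SD 0.18 on the log scale), producing realistic
test-retest variability on top of fresh noise realizations.

What the simulator does *not* emulate: multibody dynamics and linear
acceleration artifacts (the sensor model is pure gravity, by design, so
the angle inversion is exact and testable), dystonic or ataxic movement
phenotypes, learning effects across trials, and engagement or attention
lapses. Passing recovery tests therefore shows the analysis chain is
correct and sensitive under the stated noise model — not that the
instrument is valid in patients; that evidence must come from recorded
cohorts.

## The psychometric battery

**Discriminative validity.** Patients and controls are compared at fixed
ages (9.5, 12.5, 15.5 years) with a robust bootstrapped ANCOVA built on
a running-interval smoother: at each design point, each group's local
sample is everyone within `span × MADN` of the group's age distribution
(span 0.7), group means (no trimming) are compared, and a percentile
bootstrap (B = 2000) of the difference gives CIs that are
Bonferroni-adjusted across the three design points. The smoother assumes
nothing about the score–age relation; windows with fewer than 5 members
are skipped with a warning.

**Concurrent validity.** Spearman's rho (Pearson on midranks) for
summary scores, Kendall's tau-b for individual joints, where heavy ties
are expected from 3-level ratings; correlation magnitudes are labelled
negligible (&lt; 0.30), low (&lt; 0.50), moderate (&lt; 0.70), high
(&lt; 0.90) or very high (≥ 0.90).

**Reliability.** ICC(2,1) — single-measure two-way random effects,
absolute agreement — with mean squares from the two-way ANOVA
`score ~ subject + occasion`:

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with BCa bootstrap CIs (B = 1000, subjects resampled; bias correction
from the replicate fraction below the estimate, acceleration from
jackknife skewness). Absolute reliability uses the trial and residual
variance components: $\mathrm{SEM} = \sqrt{\sigma_t^2 + \sigma_e^2}$ and
$\mathrm{MDC}_{95} = 1.96\sqrt{2}\,\mathrm{SEM}$, the MDC also expressed
as an integer percentage of the grand mean (average of the two occasion
means). Negative ANOVA component estimates are truncated to zero before
the SEM — standard practice, and the truncation is explicit and warned
about rather than silent. A Wilcoxon signed-rank test (exact null
distribution for ≤ 25 untied pairs, tie-corrected normal approximation
otherwise) checks for systematic test–retest shifts, and the fraction of
participants whose baseline score exceeds the MDC (i.e. who could
improve measurably without crossing 0, the best possible score)
quantifies ceiling room. Participants missing a retest are excluded
listwise.

**Power.** The smallest correlation detectable at given n, alpha and
power solves the Fisher-z equation with small-sample bias term,
noncentrality $\sqrt{n-3}\,(\mathrm{atanh}\,r + r/(2(n-1)))$; at n = 20,
alpha = .05, power = .80 this gives r = 0.58.

## Numerical and design choices

* **Accuracy is scaled but not centred** (error / adult SD): the score
  is defined as an error standardized *to* the adult SD, keeping 0 as
  the perfect-trace anchor. A `centered_accuracy` switch exposes
  (error − adult mean)/SD. The IMS *is* centred, per its definition as
  an excess over the adult mean.
* **Error norm**: RMSE in normalized screen units, the standard
  trajectory-error norm; the accommodation phase never enters.
* **Movement metric**: mean absolute angular speed. RMS or path length
  differ only by constants on smooth signals.
* **Reference contexts** pool left and right target joints by mirroring
  (non-target joints are keyed ipsi/contra relative to the target),
  keeping all 31 adults in every cell.
* **Band edges**: correlation bands closed as printed; ICC bands use
  [0.5, 0.75) moderate, [0.75, 0.90) good, ≥ 0.90 excellent.
* **Bonferroni** across the three ANCOVA design points, the simplest
  defensible multiplicity adjustment for three preplanned comparisons.
* **BCa ties**: replicates equal to the point estimate count half
  toward the bias-correction fraction; a degenerate bootstrap
  distribution returns the point interval. With bias and acceleration
  forced to zero the interval reduces algebraically to the percentile
  interval, which the tests exploit as a closure check.
* **Determinism**: every stochastic routine takes a seed and uses a
  self-contained RNG stream, so pipelines are pure functions of
  (config, seed) and generators do not disturb the caller's RNG.

## Problem sizes in the test suite

Unit tests run on a reduced study (6 per group, 25 Hz, 12 s test phase)
so the suite stays fast; the end-to-end scientific checks use the full
design — 31 adults, 31 controls and 50 patients at 50 Hz with the
standard 25 s + 30 s phases — for parameter recovery and the group
ANCOVA, 200 × 2 synthetic designs for ICC recovery, and exhaustive
small-n enumeration for the rank statistics and the exact Wilcoxon test.

## Limitations

The generator's impairment distributions are plausible, not estimated
from data; absolute agreement with any real cohort's medians is outside
what simulation can establish. The angle model ignores transverse- and
frontal-plane movement and gyroscope fusion. Trunk involvement is
visible to the simulated therapist but not to the six sensor pairs, so
the IMS cannot capture it — a faithful reflection of the hardware.
Responsiveness (minimal clinically important difference) is not
addressed.
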