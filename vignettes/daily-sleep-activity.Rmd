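---
title: "Scoring and modelling daily sleep–activity coupling from dual-device actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modelling daily sleep–activity coupling from dual-device actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
library(dplyr)
```

`actisleep` studies how an adolescent's nightly sleep and daytime
physical activity predict one another day by day. Sleep is scored from a
wrist accelerometer (30-second epochs of activity counts, an off-wrist
flag, and white-light lux); physical activity is classified from a hip
accelerometer (1-second vertical-axis counts). Because days are anchored
at successive sleep onsets rather than at midnight, each "day" carries
one night of sleep and the waking day that follows it, and the two
temporal directions — last night's sleep predicting today's activity,
and today's activity predicting tonight's sleep — can be modelled
without constraining days to 24 hours.

This vignette documents the methods: the scoring rules and their
thresholds, the alignment and validity filters, the mixed model and its
estimation, the synthetic-data generator that underwrites every test,
and the numerical choices made where published descriptions were
ambiguous or silent.

## Sleep scoring from wrist epochs

An epoch is *quiescent* when its count is at or below
`count_threshold = 10` and the device is worn; off-wrist epochs are
excluded from every count-rule scan so that non-wear zeros cannot
masquerade as sleep (they break quiescent runs rather than extending
them).

* **Onset** — scanning forward through a rest segment, the first epoch
  of activity above 10 counts that is followed by
  `quiet_run = 5` consecutive quiescent epochs. Published rule text
  names the *active* epoch; actigraphy software conventionally reports
  the start of immobility, one epoch later. The two differ by exactly
  30 s, so both are offered (`sleep_opts(onset_epoch = "quiet")`, the
  default, or `"active"`), and the tests pin both behaviours.
* **Offset** — the mirror rule scanned from the end of the rest period:
  the first above-threshold epoch following five quiescent ones, i.e.
  the waking epoch itself.
* **Rest periods and splitting** — candidate rest blocks are quiescent
  runs of at least 5 minutes; blocks separated by less than 3 hours of
  wake form one rest period, which is then split wherever a contiguous
  wake run lasts at least 60 minutes (120 epochs), each piece being
  re-scored for its own onset and offset. Pieces shorter than 20
  minutes are discarded. The 5-minute seed and 3-hour merge radius are
  implementation choices (no published values exist); they are
  deliberately far from the 60-minute split rule so that the split
  threshold, not the merge radius, decides interval structure.
* **Main sleep vs naps** — intervals are assigned to noon-to-noon
  cut-point days by their onset. The main sleep of a day is the
  interval with the longest duration among those overlapping the
  22:00–08:00 window. The published phrase "longest duration between
  the hours of 10 PM and 8 AM" is ambiguous between total duration and
  within-window duration; the default compares total duration
  (`main_rule = "total"`), with `"within_window"` available. Ties break
  by larger window overlap, then earlier onset.
* **Within-interval sleep/wake** — no published wake-scoring rule
  exists for the interior of an interval, so the onset/offset threshold
  is reused: worn epochs above 10 counts are wake. Sleep maintenance
  efficiency (SME) is 100 × sleep minutes / (offset − onset) minutes.
* **Day validity** — a sleep day is invalid with ≥ 240 min total
  off-wrist time (first and last recording days exempt), with under
  120 min of wear before onset on the first day, or when any off-wrist
  run of ≥ 60 min starts or ends within 10 min of the main-sleep onset
  or offset.

## Activity classification from hip counts

* **Non-wear** (90/2/30 rule, minute level): maximal spans of
  zero-count minutes, allowing interior nonzero interruptions of at
  most 2 minutes when flanked on both sides by at least 30 consecutive
  zero minutes; spans of ≥ 90 minutes are non-wear. "Zero count" means
  the minute's summed 1-s counts are zero. Edge semantics (how
  interruptions chain) are pinned by a brute-force pointer-walk oracle
  in the tests.
* **Features** per 60-second window: the 10th/25th/50th/75th/90th
  percentiles of the sixty 1-s counts, using type-7 linear
  interpolation between order statistics (no published convention;
  fixed and documented here — counts 1..60 give a median of 30.5), and
  the lag-1 sample autocorrelation, defined as 0 for a zero-variance
  window so idle minutes have finite features.
* **Classifier** — the published activity-type network's weights are
  not available, so the package ships a trainable stand-in: a
  single-hidden-layer feed-forward network (`nnet`, 8 hidden units,
  weight decay 10⁻³) on standardised features, deterministic given its
  seed. It is deliberately behind a function interface: any callable
  mapping features to the five raw classes (sedentary, light,
  moderate-to-vigorous games/sports, walking, running) can replace it.
  MVPA is the collapsed moderate-to-vigorous ∪ walking ∪ running class.
  Non-wear minutes are removed before classification; accounting is
  conservative (labeled + non-wear + dropped partial minutes = stream
  minutes).

## Person-days and daily totals

A day runs from one valid main-sleep onset to the next. When the
terminating night has no valid main sleep, the day is force-ended at
the first of: the start of an off-wrist run longer than 60 minutes, or
the onset of an apparent (scored but unvalidated) sleep interval —
found by the same scoring rules — or the end of the recording.

Within each day's wake portion (offset to day end): daily MVPA minutes;
daily sedentary minutes excluding any minute overlapping a scored nap
interval (the wrist device sees the nap, the hip device calls it
sitting); the non-wear percentage of the wake portion, whose
denominator excludes scored sleep (an open choice — naps are not wake
time, so they should not dilute the percentage); and the densest
two-hour MVPA cluster, found by sliding a 120-minute window in 1-minute
steps and keeping the earliest maximising window. The reported cluster
midpoint is the window center by default; `cluster_rule = "centroid"`
reports the mean time of the MVPA minutes inside the window instead,
since the published phrase "midpoint time of the largest number of
minutes of MVPA" admits both readings. A day's activity totals are
invalid when over 25% of the wake portion is non-wear or a force-ended
day is shorter than 20 hours. Cohort inclusion requires at least three
*consecutive* valid sleep days and at least three valid activity days;
the school-year filter keeps participants whose first valid day falls
in September–May.

Sleep timing enters analysis on two clock scales: onset as
*midnight-centered* signed hours (22:00 → −2.0, 00:04 → +0.067,
continuous across midnight), offset as hours since midnight of the wake
day. The weekend indicator is direction-specific — Friday/Saturday
*nights* for sleep outcomes, Saturday/Sunday *days* for activity
outcomes — because a single "weekend" flag conflates two different
exposures; both derive from the day's anchor.

## The two-level model

For person *i* on scored day *t* (day index *d*, so a skipped day
widens the gap):

$$y_{it} = \mathbf{x}_{it}'\boldsymbol\beta + u_i + e_{it}, \qquad
u_i \sim N(0, \sigma^2_u), \qquad
\mathrm{cov}(e_{it}, e_{is}) = \sigma^2_e\,\rho^{|d_{it}-d_{is}|}.$$

Each focal daily predictor enters twice: between-person (person mean
minus the sample mean of person means) and within-person (day minus the
person's own mean over observed days; single-day persons keep a within
component of zero). The 16-model suite crosses {onset, offset,
duration, SME} × {MVPA, sedentary} in both directions. In the
sleep-to-activity direction a record's night sleep predicts the
activity of the day it opens (same record); in the activity-to-sleep
direction a day's activity predicts the *following* record's night —
so a participant with *n* complete days contributes *n* rows to the
former and *n − 1* to the latter.

**Estimation.** β and σ²ₑ are profiled out analytically (GLS and a
closed-form variance), leaving a 2-dimensional maximum-likelihood
problem over (log λ, atanh ρ) with λ = σ²ᵤ/σ²ₑ, solved by Nelder–Mead
from three AR(1) starting values ρ ∈ {−0.5, 0, 0.5} to avoid
boundary-adjacent local optima. Persons sharing a day-gap pattern share
one correlation matrix, so each likelihood evaluation reduces to a few
small dense solves plus vectorised cross-products; balanced panels hit
a single-pattern fast path. ML is the default (REML available);
boundary estimates (λ → 0, |ρ| → 1) are reported with a warning, and
rank-deficient designs drop aliased columns with a warning rather than
failing. Standard errors come from the GLS information matrix,
σ̂²ₑ(X'W⁻¹X)⁻¹, with Wald z p-values — no denominator-degrees-of-freedom
correction is attempted, a documented limitation that makes the tests
slightly liberal in small samples (the type-I simulation below measures
the realised size). The structured likelihood is verified against a
dense multivariate-normal evaluation of the full block covariance
(agreement to 10⁻⁸ on all toy cohorts up to 10 persons × 5 days), and
whole fits against an independent mixed-model implementation
(`nlme::lme` with `corAR1`), which matches coefficients and
log-likelihood to at least four decimals.

`scale_coefficient()` converts a fitted per-minute coefficient to the
effect of one additional predictor hour: ×60, and ×60 again when the
outcome is on the hours clock scale (so −0.005 h/min → −18 min/h, and
0.17 min/min → 10.2 min/h).

## The synthetic-data generator

Every downstream stage is validated against cohorts with known truth,
because the raw study recordings are not public. The generator draws a
day-level structural panel and then renders it into raw streams.

**Structural model.** Each outcome (onset, offset, SME, MVPA,
sedentary; duration is derived as offset − onset) is person intercept +
share-centered sex and weekend contrasts + coupling × person-centered
predictor + stationary AR(1) noise (lag-1 correlation `ar1_rho`,
default 0.2). Defaults emulate a school-year adolescent cohort: onset
00:04, offset 07:49, SME 90.9%, MVPA 45 min/day, sedentary 390 min/day,
with weekend shifts (+0.93 h onset, +1.86 h offset, −21 min MVPA,
−18 min sedentary on the direction-appropriate weekend) and a male
contrast on each outcome. Between-person SDs are free parameters (no
published variance decomposition exists); the defaults (1.0 h sleep
timing, 18 min MVPA, 65 min sedentary, residual SDs 0.75 h / 17 min /
65 min / 1.7%) make the marginal SDs plausible without asserting a
decomposition. Effects are share-centered so the configured means *are*
the cohort's marginal means.

"Person-centered predictor" is implemented the way within/between
decompositions define it: centered at the person's *realized* mean over
the study days. When activity does not depend on sleep (no
sleep-to-activity coupling — the default and the recovery design), the
whole activity series is realised first and the activity-to-sleep
coupling is applied to deviations from the realized person mean, so the
generating model coincides exactly with the estimand the estimator
targets and recovery is a clean unbiasedness check. (Centering at the
*latent* person mean instead differs only by a person-level constant,
which the random intercept and the between term absorb.) When both
coupling directions are active the system is genuinely simultaneous,
generation proceeds sequentially in time (night → day → night), and
latent-mean centering is used for whichever predictor is not yet fully
realised; sign-recovery tests, not unbiasedness claims, apply to that
configuration. Coupling defaults to zero — a null cohort — and is the
knob for recovery experiments.

**Rendering.** True instants are snapped to whole minutes so the 30-s
wrist grid and the 1-min hip label grid align; realized
(rounded/clamped) values become the ground truth. Wrist counts: sleep
epochs are at or below threshold; within-night wake bouts realise the
target SME but are kept ≥ 6 minutes away from the interval edges
(arousals cluster mid-night), and the epochs flanking each true onset
and offset are forced active — together these make the count rules
recover truth exactly on clean cohorts, the basis of the
pipeline-conservation check. Daytime worn epochs fall at or below the
threshold with probability `wake_quiet_prob` (3%), as isolated
stillness. Hip counts are drawn per minute label with class-specific
1-s distributions (sedentary: mostly zeros with brief fidgets; walking
and running: smooth autocorrelated streams at distinct levels;
games/sports: bursty, high-variance), so the classifier is learnable
but not trivially so. The hip device is "off" overnight (zeros), which
the non-wear rule correctly flags without touching the wake portion.
Naps, daytime non-wear gaps (Poisson per day and device), and
per-participant RNG substreams complete the picture. The global seed
seeds a master stream from which one well-mixed sub-seed per
participant is drawn; all of a participant's draws then come from that
sub-seed, and the day-level structural draws are a fixed prefix of
them, so `simulate_daily_truth()` and `generate_cohort()` are
draw-identical. Sub-seeds are drawn *through the RNG* rather than
computed arithmetically from the global seed: additive schemes such as
`seed + index` make nearby global seeds silently reuse each other's
participant streams, and even non-overlapping arithmetic families of
integer seeds produce measurably cross-correlated Mersenne–Twister
streams — either way, "independent" replications keyed by different
seeds are not independent. The replicate seeds of the validation
studies are drawn the same way.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: no seasonal or photoperiod structure, no
raw tri-axial waveforms (counts are drawn directly per class, so
classifier accuracy here does not transfer to real devices), no
postural misclassification of standing-still time, no diary-free
scorer disagreement, and clock time is naive local time without DST.
Conclusions from the validation studies concern the *pipeline's rules
and estimator*, not device physics.

## Validation studies and problem sizes

The test suite and the acceptance script run four study designs, sized
to be informative while keeping the default runs comfortably
interactive:

* **Rule–oracle equivalence**: 1,000 random count series (onset/offset,
  both conventions) and 500 random zero-sparsity series (non-wear)
  against literal brute-force scans; the requirement is zero
  discrepancies.
* **Likelihood oracle**: all toy cohorts up to 10 × 5, with and without
  day gaps, at random parameter values; agreement within 10⁻⁸.
* **Recovery**: 100 cohorts of 400 × 7 with coupling −0.005 h/min and
  ρ = 0.2; the mean estimate should sit within 2 Monte-Carlo SEs of
  truth and 95% Wald CI coverage within [0.90, 0.99]. A 2-MC-SE bias
  gate is itself a statistical test with ~5% false-alarm probability at
  any fixed seed, which is worth remembering when reading a single
  batch.
* **Type-I error**: 1,000 null cohorts of 100 × 7; the within-person
  Wald test should reject at a rate within [0.03, 0.07] at α = 0.05
  (Wald z without small-sample df correction runs slightly liberal).
* **Conservation**: a noise-free cohort pushed through the entire
  pipeline with the oracle classifier must reproduce every true
  onset/offset within one 30-s epoch and every daily MVPA/sedentary
  total exactly.

## Known limitations

* Wald z inference without Satterthwaite-style degrees of freedom; no
  multiple-testing adjustment across the 16 models (matching the
  analysis design the package implements).
* Random intercepts only — no random slopes and no non-Gaussian
  outcomes.
* The reference classifier is a synthetic stand-in; real deployments
  should plug in a classifier validated on their device and population.
* The main-sleep window rule and the cluster midpoint are implemented
  under documented default readings of ambiguous prose, with the
  alternative readings available by configuration.
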