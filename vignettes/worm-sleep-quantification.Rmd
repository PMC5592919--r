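---
title: "Quantifying developmentally timed sleep in C. elegans: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developmentally timed sleep in C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormsleep)
```

## The measurement problem

*C. elegans* sleeps in a developmentally timed way: at the end of each
larval stage, during a period called lethargus, animals cycle between
sleep bouts (complete immobility, raised arousal threshold) and motion
bouts. In the L4-to-adult (L4/A) lethargus, sleep bouts occupy roughly
30% of the period. Screens for sleep genes need to quantify this behavior
in two very different recording regimes:

* **population tracker recordings** — many animals on a plate, each
  yielding a velocity time series for a short sampling window; and
* **single-animal chamber recordings** — one animal per microfluidic
  chamber imaged every 10 s for many hours, yielding an image stack rather
  than a velocity trace.

`wormsleep` implements both quantifications on a shared bout-detection
kernel, the decision rules of a three-stage suppressor screen built on
them, and simulators that generate each input kind with known ground
truth. This vignette records the models, the conventions chosen where the
protocol leaves room, and what the synthetic data do and do not establish.

## Sleep-bout detection

A sleep bout is a maximal run of consecutive tracked samples with velocity
at or below `eps`, whose span (run length x sampling interval) is at least
`min_bout` = 10 s. Conventions:

* **Intervals are half-open** `[start, end)` in seconds; a run of `k`
  samples at interval `dt` spans exactly `k * dt`. This makes duration
  arithmetic exact and bouts non-overlapping by construction.
* **`eps` defaults to 1e-3 mm/sec.** The bout definition is "velocity
  0 mm/sec", but tracker output is floating point; a small tolerance
  absorbs numeric jitter without changing bout structure. The simulator's
  jitter mode (`sleep_jitter_sd`) exists to exercise exactly this
  tolerance.
* **The 10 s minimum is inclusive** ("at least 10 sec" read as >=).
* **Untracked samples break runs** and count toward neither sleep nor
  tracked time; plate trackers lose animals, and all population metrics
  divide by *tracked* time only.
* **No edge censoring.** A motionless run touching the start or end of a
  trace is a bout if long enough. The protocol states no censoring rule,
  and any correction would bias the pooled metrics asymmetrically. The
  cost is a small negative bias in window-sampled sleep fractions:
  partial bouts clipped below 10 s at the window edges are dropped
  (about 0.25 percentage points of FPS for the default bout process —
  well inside sampling noise at the problem sizes used here).

Both entry points — velocity traces (`detect_sleep_bouts()`) and
pre-binarized quiescence sequences (`bouts_from_binary()`) — share one
run-length kernel, and the test suite checks them against a brute-force
interval-enumeration oracle exhaustively for every binary sequence up to
length 12, and against an independent scanning oracle on long random
input.

## Population metrics (tracker assay)

FPS, BF and MSBD are *pooled* ratios: total sleep time, bout count, and
tracked time are summed across all animals before dividing. The metric
definitions say "for all animals"; pooling (rather than averaging
per-animal fractions) follows that wording, weighs animals by their
tracked time, and makes the identity FPS = BF x MSBD hold exactly
whenever there is at least one bout. With no bouts, MSBD is reported as
`NA`, never as zero. BF is kept in bouts per second internally (seconds
are the only internal time unit; minutes and hours appear only in
printed output).

## Chamber pipeline (single-animal assay)

**Frame subtraction.** For each consecutive frame pair, pixels whose
absolute intensity difference exceeds `pixel_thresh` (fraction of dynamic
range) are "changed"; the pair is quiescent when at most `area_thresh`
pixels changed. The original analysis used unpublished thresholds, so
both are explicit, tunable parameters here with defaults
`pixel_thresh = 0.1` and `area_thresh = 5` — permissive enough that
sub-threshold sensor noise never trips a pixel, strict enough that a
body-length displacement (which changes about twice the animal's area in
pixels) always does. Raising `area_thresh` can only increase the number
of quiescent pairs (a tested monotonicity).

**Timestamps.** Pair `i` (frames `i`, `i+1`) covers `[(i-1)dt, i*dt)`: a
movement is detected only once the second frame exists, and boundary
times are reported at the covering interval's start. This makes an ideal
square-wave quiescence profile yield exact entry and exit times.

**Rolling fractional quiescence.** The 10-min rolling average of the
binary calls (60 pairs at 10 s). The window is *centered*: trailing
windows would lag both boundaries by up to half a window systematically,
while a centered window has no systematic offset — though whether the
original implementation trailed or centered is unknown, so boundary
estimates may differ from the original by up to half a window. For the
even default width the center is taken as 29 entries before and 30
after; near the edges the window shrinks symmetrically to
`[i - m, i + m]`, `m = min(i-1, n-i)`, keeping the output the length of
the input. The tests compare every value against a brute-force windowed
mean implementing the same published rule independently.

**Boundary rules.** Entry `T_start` is the first time from which
fractional quiescence stays strictly above 0.1 for at least 20 min; exit
`T_end` is the first later time from which it stays at or below 0.1 for
at least 20 min. Reading "stayed above" as `>` and "dropped to and stayed
below" as `<=` makes the two rules exactly complementary at the
threshold value. Two guards:

* entries earlier than `min_onset` (default 1 hr) are rejected — animals
  are loaded at mid-L4, and lethargus is defined behaviorally as
  quiescence appearing at least 1 hr after that stage;
* if quiescence persists to the end of the recording without a
  qualifying exit (a trailing below-threshold run shorter than 20 min),
  the animal is flagged *censored* rather than assigned an exit: the
  12-hr recording is supposed to encompass the whole lethargus, so a
  missing exit signals an input-quality problem, not a measurement.

A recording in which no entry qualifies returns "no lethargus detected"
(`NULL`), distinct from validation errors.

**Per-animal metrics.** Within `[T_start, T_end)`, quiescence calls are
segmented with the shared bout kernel (each 10 s quiescent pair already
meets the minimum), giving total sleep, bout count, MSBD = total sleep /
bout count (undefined when there are no bouts) and lethargus duration.

## Screen triage

* **Primary retention**: keep a line when Ans animals are at most 30% of
  those scored (boundary inclusive; up to 10 animals per plate). Control
  populations run at a 60% per-animal Ans rate, so a control-like plate
  of 10 is retained with probability `pbinom(3, 10, 0.6)` (about 5.5%) —
  the false-positive rate the rescreen stage exists to remove.
* **Secondary selection**: the published selection regions for FPS are
  shown graphically but not numerically, so selection is a symmetric
  rule — a line is selected when its FPS differs from the control mean by
  strictly more than `k` control SDs (default `k = 2`). Both directions
  are kept because both decreased and increased sleepers were informative.
* **Tertiary decision**: a two-sample two-tailed *equal-variance*
  (Student's, not Welch) t-test on per-animal total sleep, defect when
  `p < 0.05`. Total sleep is the gating endpoint; lethargus duration and
  MSBD are reported but not gated on, since the original multi-metric
  rule is unstated. No multiple-testing correction is applied across
  lines — per-line testing mirrors the screen's practice and is flagged
  here as a caveat, not a recommendation.
* **Fisher's exact test** uses the minimum-likelihood two-sided
  convention (sum all tables with fixed margins whose point
  hypergeometric probability is at most the observed one), implemented by
  direct enumeration and cross-checked in the tests against
  `stats::fisher.test` and a binomial-coefficient oracle for every table
  with N <= 30.
* **Saturation estimate**: expected recoverable genes =
  hits x lines-per-gene / F2 lines, rounded to the nearest integer.

## The simulators: what they emulate, what they do not

`simulate_bouts()` draws an alternating renewal process inside the
programmed lethargus window: sleep bouts as `min + Exponential` (default
mean 20 s, minimum 10 s) or shifted gamma, motion bouts exponential with
mean derived from the sleep-fraction target (about 46.7 s at the 30%
default). Choices worth knowing:

* The shifted-exponential default guarantees every generated sleep bout
  survives the 10 s detection filter, so parameter recovery tests are
  unbiased; generating sub-threshold bouts (via `min_sleep_bout < 10`)
  is a deliberate way to study filter bias, not the default.
* The true bout-duration distributions in L4/A lethargus are not
  published; these families are modeling choices. Only first moments
  (and the implied sleep fraction) are matched to the study conditions.
* The process enters lethargus in a motion bout, so it is *not*
  stationary at lethargus entry; sampling windows for recovery tests are
  taken 1 hr into lethargus, as in the real assay protocol, where the
  initial-condition bias has decayed.

`bouts_to_velocity()` renders velocity as exactly 0 during sleep
(matching the bout definition) and truncated-normal speeds (mean
0.15 mm/s, SD 0.05 — typical crawling speeds) during motion.
`render_stack()` renders the animal as a hard disk, stationary during
sleep, random-walking with reflecting boundaries during motion: frame
subtraction responds to displacement only, so no worm morphology,
posture or pumping is modeled, and none of the tests says anything about
segmentation of real worm images. Plate scores are plain binomial draws.

All generators are deterministic under a fixed seed, and every artifact
round-trips through the package's own CSV/TIFF readers.

## Problem sizes and numerical tolerances

The recovery analyses use 20 replicates of 30 animals (10-min windows at
1 s sampling) for the population metrics, and 10 rendered 6.5-hr stacks
(64 x 64 px, one frame per 10 s) for the chamber pipeline — large enough
that the mean pooled FPS across replicates sits within 3 standard errors
of the 30% target and detected boundaries fall within one rolling-window
length (10 min) of the programmed ones, small enough to re-run routinely.
Boundary recovery is a statistical property, not a worst-case guarantee:
an unlucky quiescence fluctuation near entry can delay the detected
`T_start` by more than 10 min in occasional realizations. Monte-Carlo
checks (type-I error of the tertiary t-test at 1000 simulated null
screens; plate retention against the exact binomial tail) use tolerances
set from binomial sampling theory at their simulation sizes, never from
observed outcomes.

## Known limitations

* Per-line values from the original screen's raw tracker and image data
  are not reproducible here (the data are unreleased, and the original
  binarization thresholds unpublished); the package reproduces the
  *computations*, validated on synthetic ground truth, plus the
  retrospective statistics whose inputs are printed counts.
* The velocity-smoothing applied by the original tracker software is
  unspecified; traces are consumed as given, so `eps` is the only
  denoising step.
* The centered-vs-trailing rolling-average ambiguity above.
* The package gates tertiary decisions on total sleep alone; any
  analysis that weighed lethargus duration or MSBD as co-primary
  endpoints would need its own decision rule.
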