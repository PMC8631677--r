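---
title: "Detecting beluga feeding from click-train ICI structure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting beluga feeding from click-train ICI structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belugabuzz)
```

## The model

Echolocating belugas shorten their inter-click interval (ICI) as the
two-way travel time to a target shrinks, ending prey captures in a
*terminal buzz*. The package's working model of a feeding click train is a
two-phase ICI trajectory: an approach phase with ICIs above ~9 ms that
decreases gradually, then a buzz phase — operationally, everything from the
first ICI at or below the 9 ms onset threshold — in which the ICI decreases
steadily to a minimum of a few milliseconds at capture. Social buzzes,
produced during interactions rather than prey approach, are buzzing
throughout: their ICIs are longer overall and vary irregularly, with large
alternating increments.

Two summary statistics capture this contrast:

* **minICI** — the train's minimum ICI (ms). Feeding terminal buzzes reach
  single-digit values; social buzzes do not drop below ~9 ms.
* **ICIir** — the *ICI increment range*: the **maximum** of the consecutive
  ICI differences within the buzz section. A monotonically decelerating
  feeding buzz has every increment negative, so its maximum is negative;
  an irregular social buzz has large positive upsteps.

The maximum-increment reading of ICIir deserves a note, because "increment
range" could also suggest max − min of the increments. That quantity is
non-negative by construction and cannot reproduce the negative values this
statistic must take on decelerating feeding buzzes, nor the semantics of
the classifier's "all increments no larger than the cut" condition. The
maximum increment does both, and is what the package computes.

Three further variables (maxICI, the range ICIr = maxICI − minICI, and the
OLS slope of ICI over time) complete the five-variable feature set used in
the unsupervised analysis. The slope regressor is the opening click's
elapsed time in seconds (ms/s units), because ICI is a time-local quantity;
an index-based regressor is available via `slope_on = "index"` for
comparison, since either reading is defensible.

### Buzz-section rules

For trains of known social context the whole train is the buzz section.
For feeding and unknown-context trains the section runs from the first
ICI ≤ 9 ms to the end of the train. An unknown train with no ICI at or
below 9 ms has no buzz section, hence no ICIir, and can never be called
feeding; likewise a section holding a single ICI (no increment exists).
This matters for mooring data, where context is always unknown and the
directional beam means most recorded trains are fragments.

## The two-step classifier

A mooring click train is called a *feeding event* when

1. `minICI < 8.976` ms, and
2. `ICIir < 1.49` ms,

evaluated in order, with strict inequalities, after excluding trains with
`minICI < 1` ms (surface-reflected multipath arrivals masquerade as
sub-millisecond ICIs). The constants are configuration
(`threshold_rules()`), defaulting to the published values; the
stump-derived midpoint on a given fixture is *not* substituted for them.
Note the deliberate asymmetry: step 2's cut (1.49 ms) is positive, so
mildly irregular buzzes still pass, but a section must exist and contain
at least two ICIs — "at least one short ICI" alone never suffices.

## The cluster sweep

The sweep asks whether the feeding/social split is recoverable without
labels. Its grid reproduces a 64-model design: 16 partitioning-around-
medoids (PAM) models and 48 agglomerative hierarchical models, all cut at
k = 2, scored against presumed behavior with the Fowlkes–Mallows index.

The PAM count needs a reconciliation: a full cross of three distances
(Euclidean, squared Euclidean, Manhattan), two variable sets (all five; the
minICI + ICIir pair) and two scalings gives 12 models. The stated total of
16 is reached by adding the two single-variable sets (minICI alone, ICIir
alone) × two scalings; in one dimension the three distances induce the same
medoid geometry, so a single distance is recorded for those four. The
hierarchical grid crosses complete, single, average and weighted-average
linkage with Euclidean/Manhattan × two variable sets × two scalings (32),
and adds centroid (squared Euclidean only), median (Euclidean only) and
Ward's method under both Euclidean and squared Euclidean distances — the
squared variant being classic Ward — for 4 + 4 + 8 more.

Scaling is centering to zero mean and unit *sample* standard deviation;
a zero-variance column is an error naming the column, not a silent NaN.

### Determinism and tie-breaking

The sweep must be bit-reproducible without seeds, so every tie is broken
deterministically: PAM's BUILD picks the lowest-index candidate among
equals (`which.min`/`which.max` semantics), SWAP is steepest-descent with
strict improvement, equal Fowlkes–Mallows scores keep configuration order,
the stump prefers the variable listed first in `variable_order` among
equally pure splits and the lowest cut within a variable.

### What PAM's local search does and does not guarantee

BUILD + SWAP is a local search: its result is *swap-locally optimal* (no
single medoid/non-medoid exchange lowers the total cost), which the test
suite asserts on every instance it generates. On point sets with genuine
two-group structure — the regime the buzz features occupy — the local
optimum coincides with the exhaustive-search optimum over all medoid
pairs; the suite verifies this, together with exact agreement with
`cluster::pam`, on separated two-cluster instances. On *unstructured*
point sets (i.i.d. normals) a swap-locally-optimal pair occasionally
differs from the global optimum: there exist 4-point dissimilarity
matrices whose second-best pair has no improving single swap, and the
reference implementation lands on the identical local optimum there. A
test asserting global equality on unstructured draws is retained in the
acceptance suite and fails by design on such draws; it documents the
boundary of the guarantee rather than a defect of the implementation.

### Rule extraction

`fit_stump()` performs an exhaustive single-split search: candidate cuts
are midpoints between consecutive sorted unique values of each variable,
and the split minimizing the weighted Gini impurity of the two children
wins. On class extremes of 8.92 and 9.03 ms the cut lands at 8.975 ms —
midpoint behavior consistent with a published cut of 8.976 ms derived from
unrounded source data. `rpart` reproduces the same split on separable
data and serves as a cross-check in the tests, but the hand implementation
is kept because the first-listed-variable tie rule is part of the method.

## Monitoring statistics

* **DPH** — a clock hour with at least one beluga detection of any signal
  type counts once, however many events fall in it. Daily DPH is smoothed
  with a **centered** 7-day running average (±3 days, edges shrink to the
  available window). Centered was chosen over trailing because the average
  is descriptive — it aligns peaks with their dates — rather than causal.
* **FPM** — a clock minute in which at least one feeding-classified train
  *starts* counts once; a train belongs to the minute of its first click
  (trains last seconds, so spillover is negligible).
* The monthly summary reports, over days with FPM ≥ 1 only, the number of
  such days, summed FPM, and summed *non-FPM* — detection-positive minutes
  without a feeding call on those same days, i.e. presence without
  detected feeding.
* Duty-cycled recorders appear simply as event absence; no duty-cycle
  correction is applied.

Both statistics are idempotent under event duplication by construction
(distinct-bin counting), which the tests exercise directly.

## Run-timing alignment

Individual fish travel times (whole days, tag site to weir) form an
integer-lag histogram, smoothed with a centered 5-day moving average
(shorter at the edges) and normalized. Weir counts are then shifted
*earlier* by this distribution — fish pass the river mouth before the
weir — giving `predicted(d) = Σ w(lag) · weir(d + lag)`. The predicted
calendar extends the weir range by the lag support, so the convolution
conserves total count to machine precision.

The run peak is the span from the first to the last day at or above the
90th percentile of the predicted series. Two choices here were genuinely
open:

* the percentile is computed over days with predicted count > 0 (zeros on
  the season's shoulders would deflate the threshold on long calendars),
  by linear interpolation of order statistics (R type 7);
* the peak is reported as a contiguous `[first, last]` span even if
  interior days dip below threshold — matching the single start/end-date
  convention of run-timing tables — with the dipping days listed in
  `interior_below` rather than hidden.

Because a summary column labeled "7-day average DPH" over a multi-day peak
is ambiguous between a sum and a mean, `overlap_summary()` reports both
(`dph7_sum`, `dph7_mean`), labeled.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
tested, and their defaults are the published feature ranges, not free
dials: feeding minICI in [2.3, 8.92] ms with per-train maximum buzz
increment in [−8.82, −0.42] ms and a pre-buzz/buzz mean-ICI ratio in
[2, 5]; social minICI in [9.03, 29.75] ms with maximum increment in
[2.98, 18.72] ms; the labeled fixture sized 18 feeding / 19 social like
the tag study sample.

The feeding ICI decay is shaped as a fast-then-flattening descent with the
shallowest step last, a free modeling choice constrained by the realized
feature ranges; only "gradual decrease" is documented for the real trains.
One feasibility constraint is worth recording: a buzz that starts at or
below 9 ms and whose every increment is steeper than −0.42 ms cannot
terminate above ≈ 8.5 ms, so the generator's minICI draw is internally
clamped to ≈ [2.3, 8.5]. The published 8.92 ms train presumably had final
steps shallower than 0.42 ms; the generated marginals simply occupy a
subset of the published range, and every generated feeding train still
passes — and every social buzz still fails — the two-step classifier, by
construction of the ranges relative to the cuts.

What the generators do *not* emulate: received-level and detection-range
effects, fragmentary trains from a narrow beam sweeping past a mooring,
overlapping animals, false detections, porpoise/killer-whale clicks, or
species-specific travel times (the weir season applies one lag sample to
all fish). A perfect score on the synthetic fixture therefore demonstrates
the pipeline's correctness under the published feature geometry — ranges
that do not overlap the cuts — not field performance on noisy mooring
data, where fragments lacking the terminal buzz are expected to be missed.

## Numerical choices

* The buzz-onset comparison `ICI ≤ 9 ms` carries 10⁻⁹ ms of absolute
  slack: differencing click times held in seconds leaves ~10⁻¹² ms of
  floating-point dust on a nominally exact 9 ms interval, which must not
  defeat an inclusive threshold.
* Click tables are written with `%.17g` so a written-and-re-read dataset
  reproduces features bit-identically.
* Degenerate inputs fail loudly with classed conditions: trains with < 2
  clicks (no ICI) or < 3 clicks (no increment), non-monotone click times,
  zero-variance columns under scaling, single-class stump input, all-zero
  predicted runs, empty series.
* Stream classification (`classify_stream`) skips malformed trains with a
  warning and a reported count — never silently.

## Problem sizes

The test suite runs the full 64-model sweep on the 37-train fixture,
oracle comparisons at n ≤ 10 (hierarchical, against a from-scratch
Lance–Williams recursion) and n ≤ 8 (PAM, against exhaustive medoid
search), 100-draw marginal checks per generator, and a 10,000-fish season
for lag-recovery checks — sizes chosen so the whole suite completes in
well under a minute on one core while keeping multinomial noise small
relative to the effects being asserted (the 10,000-fish pulse puts ~570
fish on the peak day, against which a ±2-day peak-recovery claim is
testable once the true arrival series is smoothed with the same 5-day
window used for travel times).

## Known limitations

* The 9 ms onset, 8.976/1.49 ms cuts and the feature ranges come from 37
  trains from four tagged whales, 13 feeding buzzes from a single animal;
  the rule's generality across populations, prey and seasons is an open
  empirical question, which is why the thresholds are configuration.
* ICIir on mooring data is computed on the onset-defined buzz section;
  whether the original mooring analysis used the section or the full
  train fragment is not documented, and the section reading is the one
  consistent with the tag-data definition.
* Timestamps are treated as local clock time with no timezone or DST
  arithmetic; inputs must arrive in a single consistent clock.
* The travel-time correction borrows one species' lags for all species and
  ignores mouth-to-tagging-site transit entirely.
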