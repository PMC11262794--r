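---
title: "Methods: from image stacks to sleep, arousal, memory and calcium metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from image stacks to sleep, arousal, memory and calcium metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvasleep)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The pipeline quantifies the behavior of
individually housed *Drosophila* larvae recorded by time-lapse infrared
imaging in a multi-well arena, together with the conditioning, feeding and
calcium-imaging assays that accompany such experiments.

## Activity by frame differencing

Each recording is an ordered stack of grayscale frames at a fixed interval
(default 6 s). For every temporally adjacent frame pair and every well
rectangle, activity is the number of pixels whose absolute intensity change
is at least a binary threshold; smaller changes count as zero ("no
change"). The stage-specific defaults are 40 gray-scale units for L2 and 45
for L3 (`default_threshold()`), the larger L3 value compensating for larger
body size; both are overridable.

Numerical conventions, stated once and used everywhere:

* "Subtraction" is the **absolute** difference. A signed difference would
  make activity depend on frame order, for which there is no rationale;
  absolute differencing makes activity symmetric in the two frames (a
  property the tests assert).
* The comparison is `>= threshold`: a change of exactly `threshold - 1`
  contributes 0, exactly `threshold` contributes 1.
* Differencing is done in double precision after reading, so 8-bit storage
  can never wrap around.
* Well rectangles are 0-based and half-open: a well covers pixel columns
  `[x0, x1)` and rows `[y0, y1)`. Activity is strictly local to the
  rectangle; a changed pixel straddling two wells is counted by exactly the
  well that owns it.

No background subtraction, smoothing or registration is applied: the method
is defined directly on raw adjacent frames.

## Sleep calls, bouts and windows

Sleep is defined as an activity value of zero between frames: interval `i`
is asleep iff `A_i = 0`. States index inter-frame intervals (interval `i`
is the change from frame `i` to `i + 1`), so a stack of `n` frames yields
`n - 1` calls. Bouts are maximal runs of asleep intervals, each lasting its
run length times the frame interval; `call_sleep()` is verified against an
independent run-length scan in the tests. The definition imposes no minimum
bout duration, so the default minimum is one interval (6 s); it is exposed
as `min_bout_intervals` for users who want a stricter criterion, and runs
shorter than the minimum are excluded from both the bout list and the sleep
totals. With the default, asleep time plus awake time exactly partitions
every analysis window.

Summaries (`summarize_sleep()`) report total sleep in minutes, bout number,
and mean bout length per larva. The standard windows — the second hour
after the molt for circadian-time comparisons, and the 6-hr window starting
2 hr after the molt for across-day comparisons — are selected with the
`window` argument; circadian labels such as CT1/CT13 are attached as
metadata, not computed, since the package deliberately implements no clock
model.

## Arousal threshold

The assay probes sleeping larvae with a low-intensity 4-s light pulse every
2 min for 1 hr; `make_schedule()` generates the 30 onsets at 0, 120, ...,
3480 s. Scoring conventions (`score_arousal()`), where the assay definition
leaves the frame alignment open:

* A larva is **tested** at an onset if it is asleep then, judged by the
  interval containing the onset having zero activity. A switch
  (`asleep_only = FALSE`) scores every larva, but the default reflects that
  the assay measures arousal *from sleep*.
* It **responds** if any interval starting within the response window after
  the onset has nonzero activity. The default window is the stimulus
  duration plus two inter-frame intervals (16 s at 6-s framing): the
  smallest window guaranteed to contain at least one full frame pair after
  the pulse regardless of phase.
* The replicate's score is 100 x total responses / total tests, pooled over
  the 30 stimuli; replicate scores are averaged downstream, matching how
  such assays report "percentage of animals that moved".

## Feeding, intake, and the performance index

Feeding rate is the mouth-hook contraction count over a 5-min observation,
stored raw (rescaling to 300 s is available but off by default, since the
standard protocol observes exactly 5 min). Food intake is the OD629 of the
group homogenate — the OD value *is* the measurement; blank correction is
optional and off by default.

For choice assays, counts on the two sides and the middle must sum to the
group size. The naive preference is `(side A - side B) / total` with A the
odorant side (or the agarose side of a quinine plate). For reciprocal
conditioning, each trained group's PREF is (CS+ side - CS- side) / total,
and the performance index is the mean of the two reciprocal PREFs. Middle
larvae are counted in the total only: the formulas divide by the total
number of larvae after three-way counting, which is the only reading
consistent with the assay description. Consequences asserted in the tests:
all scores lie in [-1, 1], PI is invariant to the order of the two groups,
and relabeling the odorants in both groups flips the sign of both PREFs and
of PI.

`permutation_compare()` is a convenience two-group randomization test on
the difference of means with add-one smoothing,
`p = (1 + #{|d_perm| >= |d_obs|}) / (n_perm + 1)`. It is meant for
screening simulated experiments; the exported mean ± SEM group tables are
intended for standard inferential workflows (ANOVA etc.), which this
package does not reimplement. Ties are counted as exceedances (with a tiny
relative tolerance so exact ties survive floating point), which makes the
test conservative on discrete data — visible as a null rejection rate
slightly below the nominal 5% in the calibration test.

## Calcium trace normalization

Per-cell raw GCaMP traces arrive as long-format tables with epoch labels
(`baseline`, a stimulus label, `washout`). `F0` is the arithmetic mean over
the **first 60 s** of the baseline epoch — exactly 60 s even if the
recorded baseline is longer — and `dF/F = (F_n - F0) / F0` with `F0` held
fixed. `dF/F_max` is the maximum `dF/F` over the stimulus epoch only:
excursions during baseline or washout are excluded. No smoothing is applied
before taking the maximum, since none is part of the quantitative
definition. `dF/F` is invariant to multiplicative rescaling of the raw
trace, which the tests assert numerically.

Epoch templates (`epoch_schedule()`): the ATP/P2X2 protocol samples every
5 s with a 1-min baseline and 2-min ATP epoch; its standard recording
length is 180 s (baseline + stimulus), while the template also describes
the 2-min buffer washout for rigs that keep acquiring — every quantity the
package computes (F0, `dF/F_max` during ATP) depends only on the first
180 s, so the two readings of the protocol timeline coincide where it
matters. The peptide bath protocol samples every 10 s for 4 min (1-min
baseline, 2-min peptide, 1-min washout), and the vehicle control uses the
same timings with a `vehicle` stimulus label. ROI extraction from image
stacks is out of scope: the quantitative definitions begin at the trace
level, and the module ingests per-cell traces.

## The synthetic-data generator

The generator exists so every stage can be tested against known ground
truth; its defaults are the study conditions, not tuning knobs.

**Behavioral states** are a two-state Markov chain per larva with
`P(ACTIVE -> QUIESCENT) = p_sleep` and `P(QUIESCENT -> ACTIVE) = p_wake`,
initialized from the stationary distribution (quiescent occupancy
`p_sleep / (p_sleep + p_wake)`) to avoid burn-in bias in occupancy tests.
Monte-Carlo checks of occupancy use the chain's correct asymptotic variance
`pi (1 - pi)(1 + rho)/(1 - rho)/n` with `rho = 1 - p_sleep - p_wake`; a
naive binomial standard error would understate the spread of so strongly
autocorrelated a sequence several-fold.

**Rendering** draws each larva as a filled ellipse (default semi-axes
4 x 2 px — any compact blob works for a differencing detector; no shape or
peristalsis model is claimed) at intensity 200 on background 30, inside
40-px wells on a grid. On ACTIVE intervals the centroid moves `move_step`
(default 3) px in a uniform random direction, reflecting off the well
walls; a move whose post-reflection displacement falls below one pixel is
redrawn so active intervals always change pixels. On QUIESCENT intervals
it holds still. I.i.d. Gaussian pixel noise (default sd 2) is added,
clipped to 0-255 and rounded.

**Clean mode** (the default) enforces two separability constraints against
the detection threshold: contrast `>= threshold + 3 sd` so real movement
always trips the detector, and `3 sd < threshold / 2` so the difference of
two noisy pixels (sd `sqrt(2) * 2 ≈ 2.8`) essentially never reaches 40 — a
14-sigma event. Under these constraints the differencing pipeline recovers
the simulated quiescence flags exactly, which the acceptance tests assert
on a 20-well, 600-frame stack with mixed occupancies.

What the generator does **not** emulate: illumination drift, vignetting,
structured camera noise, larval shape change, feeding behavior in video
(mouth-hook counts enter as plain numbers), or multiple animals per well.
Passing the recovery tests therefore shows the pipeline is a faithful
implementation of the stated definitions, not that those definitions are
robust to instrument pathologies absent from the model.

**Other inputs.** Choice counts are a single multinomial draw over
(CS+ side, CS- side, middle); under CS+ probability `p` with no middle
mass, the expected PREF is `2p - 1`, which the simulation tests recover.
Stimulus-evoked arousal places a response (a positive activity value in the
first interval after the onset) with a stated per-stimulus probability.
Calcium transients are `F0 (1 + a k(t)) + noise` with a kernel rising
linearly to exactly 1 over `rise_s` and decaying exponentially; because the
peak time `onset_s + rise_s` is a sample point under the defaults, the
noiseless sampled maximum equals the nominal amplitude exactly, giving the
normalization code an exact oracle.

## Reproducibility and problem sizes

Every stochastic function takes a `seed` and restores the caller's RNG
state; identical seeds give byte-identical outputs, including the CSVs
written by the end-to-end demo (`run_synthetic_demo()`), whose provenance
record carries the package version, configuration, config hash and seed —
and deliberately no timestamp.

The simulation studies use sizes chosen to make Monte-Carlo error small
relative to the tolerances tested: 20 wells x 600 frames for exact
ground-truth recovery; 50 larvae x 1 hr for occupancy recovery; 18 larvae
x 4 replicates x 30 stimuli for arousal calibration; 500-1000 replicate
pairs for the performance-index expectation; 100 cells for calcium
amplitude recovery; and 500-1000 simulated experiments for the permutation
test's null calibration. The demo renders two 30-larva groups for a full
hour at 6-s framing.

## Known limitations

* Well geometry is taken as given; there is no automatic grid detection,
  pose tracking, or support for multi-animal wells.
* Circadian structure is labeling only; no periodogram or phase analysis.
* The permutation comparison is the only built-in inference; group tables
  are exported for everything else.
* The Gaussian noise model is a stand-in for unspecified camera noise, not
  a claim about any instrument.
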