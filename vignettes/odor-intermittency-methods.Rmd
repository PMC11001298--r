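---
title: "Models and methods: quantifying odor plume intermittency and its encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying odor plume intermittency and its encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorint)
```

## The problem

In a turbulent odor plume, concentration at a fixed point is not a smooth
gradient but a train of brief "whiffs" separated by clean-air blanks. A
compact statistic of this temporal structure is **intermittency**: the
probability that the local concentration exceeds a threshold,

$$\gamma = \Pr\left[C \ge 0.1\, C_0\right],$$

where \(C_0\) is the source (maximum) concentration. Intermittency falls
with distance from the source, so an animal that can read \(\gamma\) can in
principle infer range. This package implements, as a tested pipeline, the
analyses needed to ask (i) whether simulated Go/No-Go behavior tracks
\(\gamma\) and the *perceived* \(\gamma\) given active sniffing, and (ii)
how olfactory-bulb glomeruli, observed through wide-field calcium imaging,
encode \(\gamma\) — together with a synthetic-data generator that supplies
ground truth for every stage.

## Stimulus quantification

A `stimulus_trace` carries concentration samples (1 kHz by default), the
gain-1 source concentration `C0`, the stimulus kind, and the gain. All
windows are half-open `[from, to)` so sample counts are exact. Conventions
that matter:

* the threshold is always \(0.1 \, C_0\) of the **gain-1** reference, never
  the trace's own maximum, so halving the gain does not move the threshold;
* threshold comparisons are inclusive (\(\ge\));
* \(\gamma\) is computed over the 6 s odor window only;
* whiffs are maximal supra-threshold runs, with no gap merging — two whiffs
  separated by a single sub-threshold sample count as two.

Square-wave stimuli with \(n\) pulses spanning 6 s at duty \(d\)% give
\(\gamma = d/100\) exactly up to sample quantization, which the tests assert
at \(1/(6 \cdot \text{rate})\). CS labelling follows the task contingency:
\(\gamma \le 0.15\) is CS−, \(\gamma \ge 0.2\) is CS+, and the gap in
between gets an explicit `excluded` label rather than a silent assignment.

## Sniffing and perceived intermittency

Sniffs are detected as positive-pressure peaks with a topographic-prominence
threshold (default twice the median absolute deviation of the trace — a
robust spread measure; a peak whose prominence search hits the record
boundary without meeting higher ground uses the interior side's base, so
first and last sniffs are not penalized by the finite window). Each onset is
the last non-positive-to-positive crossing before its peak; inhalation
intervals are `[onset, peak)`. The **estimated perceived odor** is the
concentration sequence restricted to inhalation intervals inside the odor
window, and **perceived intermittency** applies the same \(0.1\,C_0\)
threshold to that sequence, with \(T\) the total inhalation time. Trials
with \(T = 0\) are flagged `NA`, never silently zero. A cumulative variant
evaluates the same quantity on growing windows from odor onset, and equals
the full-trial value at the final time point by construction. Averaged over
uniformly random sniff phase, perceived \(\gamma\) is an unbiased estimate
of stimulus \(\gamma\) for periodic stimuli; the tests check this by Monte
Carlo against 3 standard errors.

## Imaging preprocessing

Raw per-glomerulus fluorescence at 25 frames/s passes through:

1. **dF/F** against the mean of the 100 ms immediately before odor onset;
2. **zero-phase Butterworth band filtering**, 0.075–10 Hz, 4th order per
   pass. Zero-phase (forward–backward) filtering is used so response
   latencies are not biased by filter delay; this doubles the effective
   order. Because the 0.075 Hz corner has a ~2 s memory on a 9 s record,
   edge handling matters: the implementation uses odd-reflection padding
   sized to ~2.5 slow time constants with steady-state initial conditions,
   which removes DC exactly and keeps edge transients at numerical noise;
3. **bleach correction**: a quadratic fit to the pre- and post-odor windows
   only, subtracted from the whole trace (the filter is applied first, the
   polynomial second);
4. **deconvolution** of the indicator kernel \(e^{-t/\tau}/\tau\) with
   \(\tau = 150\) ms, implemented as the exact inverse of the discrete
   first-order kernel \(y_t = a\,y_{t-1} + (1-a)\,r_t\),
   \(a = e^{-\Delta/\tau}\), initialized at steady state so constant traces
   are fixed points. No non-negativity or sparsity constraint is imposed;
   convolving the output reproduces the input to numerical precision;
5. **z-scoring** against the 2 s pre-odor baseline. A numerically dead
   baseline (SD at the trace's floating-point floor) flags the
   glomerulus-trial invalid instead of propagating infinities.

The first-sniff response window runs from the first sniff onset at or after
odor onset to the next onset, capped at 1 s — one inter-sniff interval is
the natural unit, since the bound is otherwise unspecified. Amplitude is the
trough-to-peak range of the z trace in that window; T75 is the time from
sniff onset to trough + 75% of the range, measured on the dF/F-scale trace
(the amplitude itself stays on the z scale; the two scales are kept as the
quantification defines them). Responder selection is strict at both stages:
a trial responds when amplitude exceeds a z of 2 (strict `>`), and a
glomerulus is kept when its responding-trial fraction exceeds 10% (strict
`>`), so 7 of 64 trials qualifies and 6 of 64 does not.

## Encoding statistics

**Glomerular intermittency (GI)** mirrors the stimulus statistic on the
neural side: the fraction of odor-window samples with \(Z \ge 2\)
(inclusive, as defined — note the deliberate asymmetry with the strict
responder rule; both forms are kept as printed). The **GI slope** is the OLS
slope of GI against odor intermittency across trials; its sign separates the
two planted phenotypes. The **encoding ANOVA** bins trials to intermittency
groups 0.2/0.5/0.8 (nearest target within ±0.05, out-of-band trials
dropped) and calls a glomerulus an encoder at p < 0.001.

**Shuffle-corrected cross-correlation** uses Pearson-normalized coefficients
on a ±500 ms lag grid tied to the 25 Hz imaging clock (40 ms steps);
positive lags mean the response lags the reference. The shuffle control is a
whole-trace random sample permutation of the rate (destroying temporal
structure, preserving the marginal), averaged over 10 iterations and
subtracted per lag. At lag 0 the raw coefficient equals the direct Pearson
correlation exactly, which the tests assert at 1e−10.

## Clustering and decoding

GI tuning profiles (mean GI per intermittency bin, 0.1–0.8 in 0.1 steps)
are correlated between glomeruli; hierarchical clustering runs on the
correlation distance \(d = 1 - r\) with the tree cut at 0.74. Single
linkage is the default (the classical default of the linkage routine the
procedure names), with average linkage available.

The decoder is a linear discriminant with class means, pooled covariance and
equal priors, written in-package because the procedure prescribes
training on **one third** of trials and testing on the remaining two thirds
(the reverse of the conventional split), stratified by intermittency value,
repeated 20 times with derived sub-seeds. When the pooled covariance is
singular or the training count does not exceed the feature count, a ridge
term \(\lambda = 10^{-6}\,\mathrm{tr}(S)/p\) is added. Accuracy is correct
predictions over test trials; the true-positive rate is correctly predicted
CS+ over CS+ test trials. With zero features the classifier falls back to
the prior and sits at chance.

## Go/No-Go behavior

Outcomes depend only on licks inside the decision window (1.5 s beginning
0.5 s after odor offset, when the decision tone ends); anticipatory licks
are recorded but never change the outcome. Engagement trimming discards all
trials up to and including the fourth hit — read as the fourth *cumulative*
hit, not four consecutive (both readings coincide on sessions opening with
the high-intermittency engagement block; a flag selects the consecutive
reading). HR and FA are exact counts; the learning criterion is strict
(HR > 0.75 and FA < 0.25). Trials in the excluded CS gap are dropped from
metrics. First-lick times are referenced to odor onset. Decoding trial
identity from cumulative perceived intermittency uses the same
cross-validated discriminant on a single feature per time cutoff, with a
shuffled-label control through the identical pipeline and Bonferroni
correction across cutoffs.

## The synthetic generator and what it does (and does not) emulate

The generator defines the study conditions the tests run under.

* **Plume traces**: whiff/blank alternation is a two-state renewal process
  with exponential durations (the simplest memoryless process with a
  tunable duration fraction; the source plumes' higher-order temporal
  statistics are not parameterized anywhere we could draw them from, so the
  generator matches intermittency only). Mean whiff duration defaults to
  0.2 s, a realistic near-source whiff scale. The whiff/blank sequence and
  plume texture are drawn once per trial; the blank mean duration is then
  rescaled by geometric bisection (realized duty is monotone in the blank
  scale) until the realized intermittency, recomputed with the package's own
  statistic, is within ±0.02 of target, re-drawing the sequence if an
  over-long opening whiff makes a low target unreachable; failure after 50
  evaluations is an error naming the target and the last realized value.
  Naturalistic texture adds within-whiff depth modulation and 40 ms
  smoothing before normalizing the peak to \(C_0\).
* **Sniffing**: biphasic cycles (positive inhalation lobe, shallower
  negative exhalation lobe) with optional period jitter and phase; ground
  truth onsets/peaks are returned for recovery tests.
* **Glomeruli**: two phenotypes. Whiff-driven (cluster 2) units are active
  when the sniff-sampled concentration is high; blank-driven (cluster 1)
  units when it is low within the odor window — the minimal generative rule
  producing the inverse GI relationship. Each unit carries a planted GI
  line; the preset cluster slopes are +0.89 and −0.59 with intercepts 0.05
  and 0.65 (keeping GI inside [0, 1] over the 0–0.8 range). An optional
  per-unit slope SD adds the population diversity real data show. Response
  gain and latency rise along a posterior-lateral gradient of the 256×256
  frame so spatial-map analyses have planted signal.
* **Fluorescence**: the phenotype drive is sniff-gated by sample-and-hold at
  each inhalation, converted to a binary activity mask whose odor-window
  duty equals the planted GI value for that trial (most-driven samples
  active), delayed by the unit's latency, scaled, convolved with the 150 ms
  kernel, and combined with baseline fluorescence, quadratic bleaching
  drift, and white noise. The default noise level places first-sniff
  response amplitudes near 5–7 z units, the scale typical of wide-field
  GCaMP6f glomerular data. The *declared ground-truth rate* is the planted
  activity passed through the pipeline's linear measurement operator (band
  filter plus baseline-window quadratic projection): a 0.075 Hz high-pass
  on a 9 s record necessarily discards some trial-scale structure, so the
  recoverable quantity is the measurement-band component, and that is what
  parameter-recovery tests compare against (they achieve r > 0.99 with zero
  noise).
* **Sessions**: the default layout is 8 high-intermittency engagement
  trials followed by 28 CS+ and 28 CS− in random order with gains 1 and 0.5
  balanced; an explicit per-trial intermittency list overrides this for
  anesthetized-style imaging sessions. Licking follows a logistic policy on
  the trial's estimated perceived intermittency (midpoint 0.175, between
  the CS bands), with first-lick latency decreasing in perceived
  intermittency and a ~7 Hz lick train through the decision window on
  "lick" trials. Because the policy reads *perceived* intermittency,
  sessions with adjacent CS bands reproduce imperfect, realistic hit and
  false-alarm rates; deterministic behavior requires bands separated by
  more than the sniff-sampling error.
* **Reproducibility**: one base seed per session; every trial, glomerulus
  and noise stream uses a sub-seed from a stable polynomial hash, so adding
  a glomerulus does not perturb the others, and identical seeds give
  byte-identical sessions.

The generator does **not** emulate spatial plume physics, pupil or
locomotion signals, imaging motion artifacts, or ROI segmentation; passing
tests therefore validate the analysis chain, not those upstream stages.

## Numerical choices and problem sizes

Recovery suites run at deliberately modest sizes chosen to give stable
statistics: GI-slope recovery uses 50 units × 180 trials (60 per
intermittency group); cluster recovery uses the 37/191 two-population
layout with 24 trials spanning the 0.1–0.8 range; decoding uses 25 units ×
120 trials with separated CS bands (a training fold must exceed the feature
count for a full-rank pooled covariance — with fewer trials the
ridge-regularized discriminant plateaus around the high-0.8s, as seen in
comparable real datasets). The shuffled-label control is averaged over
many label permutations, because with near-noiseless features a single fixed
permutation retains exploitable chance association with the stimulus.

## Known limitations

* The measurement-band definition of the ground-truth rate makes the
  zero-noise recovery invariant a statement about the band-limited
  component, not the raw binary activity — inherent to a 0.075 Hz high-pass
  on 9 s records.
* T75 resolution is one imaging frame (40 ms), so latency comparisons are
  rank-based, not metric.
* The permutation check of the encoding ANOVA compares a parametric p-value
  with an exact resampling p-value; they agree closely on well-behaved
  instances but are not identical estimators.
* Session persistence uses native R serialization plus a CSV trial table;
  interchange with other toolchains should go through the CSV outputs.
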