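---
title: "Methods: reinforcement-gated ensemble recall in maze inter-trial intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reinforcement-gated ensemble recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensemblerecall)
```

## The scientific question

During Y-maze rule learning, a rat finishes each trial at the end of a goal
arm, consumes any reward, and makes a self-paced return to the start
position. These inter-trial intervals (ITIs) are the window in which a
short-term memory of the just-finished trial could be held in medial
prefrontal cortex. The package asks four questions of simultaneously
recorded populations:

1. Does the same pattern of pairwise neuron co-activity recur across ITIs,
   and is that recurrence gated by the outcome of the preceding trial?
2. When within a session does the recalled pattern switch on and off, and
   how does that relate to the behavioural learning trial?
3. Is the ITI pattern a replay of the preceding trial's pattern?
4. Which task features (prior/next outcome, arm, cue) can be decoded from
   the population's position-resolved firing rates, and where on the maze?

## The recall statistic

For a session with `T` ITIs, the *core population* is the set of `N`
neurons with at least one spike in every ITI; using a fixed population
keeps every ITI's similarity matrix the same size. Each spike train is
convolved with a Gaussian kernel (width `sigma`, default 100 ms, supported
range 20-240 ms) on a uniform grid (`dt`, default 10 ms, always at most
`sigma/5`), then z-scored with the mean and standard deviation pooled over
all ITIs of the session.

The co-activity of ITI `t` is the `N x N` matrix `S_t` whose entry
`(i, j)` is the *rectified correlation* of the two neurons' normalised
densities within the interval: the uncentered (cosine) correlation,
truncated below at zero. Rectification matters because the comparison of
two co-activity patterns must distinguish co-activation from
co-suppression: without it, two intervals in which the same pairs were
*anti*-correlated would count as recall of the same pattern.

The session-wide normalisation matters too, and this is a deliberate
reading of an ambiguity. If within-interval Pearson correlation were used
for `S_t`, the z-scoring step would be provably inert (Pearson is
invariant to per-neuron affine maps), and — as shown below — the
duration-bias null model could not work even in principle. With the
cosine convention, a neuron's deviation of interval-mean rate from its
session mean contributes to similarity, which is exactly the quantity the
ISI shuffle preserves.

Recall between two ITIs is the rectified Pearson correlation of the
upper-triangle vectors of `S_t` and `S_u`; collecting all pairs gives the
`T x T` recall matrix `R`.

## The duration-bias null model, and what it can and cannot remove

ITIs after correct trials are much longer than after errors (the animal
lingers at the reward port; the generator defaults are 79.1 s vs 48.4 s),
so post-correct interval pairs could look more similar merely because
their co-activity is estimated from more spikes. The null model shuffles
each neuron's inter-spike intervals within each ITI (preserving count,
duration, first-spike offset, and the ISI multiset), rebuilds the full
recall matrix, and averages over `n_shuffles` (default 1000) surrogates;
the residual matrix is the data matrix minus this expectation.

Working through the estimator mechanics (and confirming by simulation
with the package's own generator) clarifies exactly which biases the
shuffle can capture:

* Effects that are functions of spike **counts and ISI statistics** are
  reproduced *exactly* in every surrogate, because the shuffle preserves
  them. These include the interval-mean rate offsets that enter the
  cosine similarity, and they always make *short*-interval blocks more
  self-similar (short intervals deviate more from the session mean in a
  shared, duration-determined direction), so the expected matrix's block
  difference is at most zero.
* Effects that ride on **temporal structure** — a co-fluctuation pattern
  expressed in every ITI, whose correlation estimate is more reliable in
  longer intervals (the attenuation mechanism) — are destroyed by the
  shuffle. A raw bias of this kind therefore passes through to the
  residual matrix essentially unchanged.
* For stationary surrogate trains, the expected recall between two
  intervals is *flat in duration*: the mean and the standard deviation of
  every similarity entry both scale as one over the square root of the
  interval length, and the vector-level correlation cancels this common
  scale.

The practical consequence: the residual correction removes the
rectification floor and every count-driven artefact, but a raw recall
difference caused by reliability of estimation on top of genuine shared
structure is, with this null, not removable. The acceptance suite states
this honestly: its duration-bias check generates null sessions whose only
fast structure is an outcome-independent background co-fluctuation, shows
that the raw block difference is positive, and then applies the
two-standard-error test to the residual — which documents the size of the
surviving attenuation bias rather than certifying its absence.

## Block comparisons and the pair-counting convention

Outcome (or arm, cue, next-outcome, path-length) comparisons collect the
within-group entries of the residual matrix and compare the two
distributions by a two-sample Kolmogorov-Smirnov test, summarised by
`delta`, the difference of the two block means. By default the blocks are
the off-diagonal upper-triangle pairs of each group, because the diagonal
self-similarity is 1 by construction and carries no information. A
`counting = "full"` option includes the complete block (diagonal and both
triangles), the convention implied by published `k x k` pair counts; both
are implemented because the source material is internally inconsistent
about it, and no analysis in this package depends on the choice.

## Onset and offset of the recalled pattern

For each admissible dividing ITI (at least 3 ITIs before, 5 after), the
within-block recall values before and after are compared. The dividing
ITI with the largest *increase in mean recall* is the onset candidate,
accepted if the two-sample KS test at that split reaches `alpha` (0.05)
and the signed KS distance agrees in direction; the offset is the
analogous largest decrease. Selection by the mean shift matters: blocks
of only three ITIs contribute three pair values, and the supremum of an
empirical-CDF difference over three points is so volatile that selecting
on the KS distance itself hands the argmax to these flukes (in
simulation, window recovery drops from 100% to 30-40%). Gating by the KS
test keeps the sweep's false-positive rate on i.i.d. matrices near 5-10%
with no multiple-comparison correction; none is applied because the sweep
is a localisation device, not a family of confirmatory tests. Onset and
offset are searched independently and their ordering is not enforced.

## Trial-versus-ITI similarity

To test whether the ITI pattern replays the preceding trial's pattern,
the same similarity machinery runs on a joint core population (active in
every trial *and* every ITI — a subset of the ITI core, since trials last
only a few seconds). For each trial/ITI pair, `R_within` compares the two
similarity matrices; the null shuffles the ITI trains (50 repeats by
default) to give the similarity expected between independently firing
groups, and a one-tailed sign test asks whether the per-pair differences
are systematically positive.

## Position-dependent decoding

The return path (goal-arm end, through the choice point, to the start-arm
beginning; 170 cm on the maze skeleton of three 85 cm arms at 120
degrees) is divided into five equal-length sections; section 1 is the
reward site, section 3 covers the choice point, section 5 the departure
point. Equal spacing is measured in path length, not occupancy time,
because the dwell at the reward site would otherwise absorb most
sections. Each tracking sample is projected onto the skeleton (samples
farther than 10 cm off-skeleton, or nearer the unchosen goal arm, are
dropped); rates are spike counts within a section's occupancy frames
divided by occupancy time, with re-entries summed.

Decoders are linear and deterministic: ridge-penalised logistic
regression (IRLS, penalty 0.01 on slopes only — enough to keep weights
finite on separable data without measurably moving the boundary; a
glmnet fit cross-checks it in the test suite), linear discriminant
analysis, a linear support-vector machine, and 1-nearest-neighbour with
distance ties resolved to the first class level. Accuracy is
leave-one-out cross-validated; chance is the same LOOCV procedure on
label-shuffled data (50 shuffles by default), with identical example
sets for true and shuffled fits, and relative accuracy is the difference
from the shuffled mean. ITIs with zero occupancy of a section, or an
undefined label (the last ITI for prospective features), are excluded
from that section's decoder.

## Behavioural analysis

The learning trial is the first of three consecutive correct trials from
which performance stays at or above 80% to the session end (the window
starting at the candidate trial; starting after the triplet is available
as an option). Note one sharp edge of this criterion: a session that
merely *ends* on three correct trials qualifies vacuously, so flat
sessions trigger it near the session end at a non-trivial rate — a
property of the criterion, not of its implementation.

The steepest-trial alternative fits two regression lines to the
cumulative reward curve around every admissible split (at least 5 trials
per side) and maximises the slope increase. The segment fits use a Huber
M-estimator with an exact-OLS fast path for perfectly linear segments.
A pairwise-median (Theil-Sen) slope was considered and rejected: it is
piecewise-constant in the split position, so the sweep ties over a
plateau around a noiseless kink and cannot localise it. Even with the
M-estimator, the generative step of a Bernoulli reward sequence is only
identifiable to within a few trials (about 60% of runs within two trials
at best, by simulation); the original criterion is the sharper detector
and is the one the recovery checks rely on.

Sessions are classified `learning` (original criterion met),
`minor_learning` (some admissible split has a positive slope increase),
or `other`. Strictly positive is used for the minor-learning rule; with
discrete staircase curves this labels some non-improving sessions
minor-learning, which matches the roughly half-and-half split such a
rule produces on non-learning sessions.

## The synthetic-session generator

The generator is first-class, tested code: every analysis above is
validated by recovering structure that the generator planted.

* **Behaviour**: outcomes are Bernoulli with a step at the configured
  learning trial (0.2 before, 0.9 after by default); arms and cues are
  drawn consistently with the configured rule, with cue sides lit
  pseudo-randomly throughout. ITI durations are gamma with shape 4 —
  positive and right-skewed, matching the lingering-at-reward asymmetry —
  with outcome-conditional means of 79.1 s (post-correct) and 48.4 s
  (post-error).
* **Tracking**: 30 Hz positions along the maze skeleton; each trial runs
  start to goal-arm end, each ITI dwells at the reward site and returns
  over `return_time_s` (15 s default). Keyframes snap to the frame grid
  so the zero-jitter return path measures the analytic 170 cm.
* **Spikes**: inhomogeneous Poisson on a 5 ms rate grid. The
  reinforcement-gated ensemble shares a unit-variance Ornstein-Uhlenbeck
  latent with 100 ms correlation time, applied as `exp(c*z - c^2/2)` only
  during post-correct ITIs inside the configured window. Two kinds of
  outcome-independent structure make the null realistic: a background
  latent with heterogeneous weights shared by all neurons in every ITI
  (cortical noise correlations; default coupling 0.4, giving mean raw
  recall of order 0.1), and per-neuron spatial rate profiles over the
  five maze sections (default log-normal, sdlog 0.4). Retrospective
  tuning for decoding tests multiplies configured neurons' rates by a
  factor in configured sections when the preceding trial has the
  feature's reference level. Spike times are rounded to 0.1 ms and
  deduplicated; all stages draw from per-stage streams derived from one
  master seed, so sessions are bit-reproducible.

What the generator does **not** emulate: realistic place fields or theta
rhythmicity, bursting/refractory ISI structure, slow within-session drift,
sleep epochs, behavioural idiosyncrasies of real rats (variable running
speed, grooming bouts). Passing tests therefore demonstrate that the
statistics recover the structures they target under Poisson-like
variability with realistic rates, durations and geometry — not that they
are robust to every property of tetrode data.

## Numerical choices and degenerate inputs

* Density grids: `dt = min(0.01, sigma/5)` seconds; kernels evaluated
  analytically at grid points, truncated at five sigma and at interval
  edges (no padding). The evaluation uses a multiplicative recurrence
  (two multiplies per grid point) whose rounding error stays near machine
  precision over a kernel's support.
* Half-open intervals `[start, end)` everywhere a spike or frame is
  assigned to an interval, so boundary events are never double-counted.
* A neuron silent (or norm-zero) within one interval contributes zero
  similarity entries, keeping matrix dimensions fixed; a constant
  upper-triangle vector yields a recall of 0 with a warning; a neuron
  with zero pooled variance across the session is an error naming the
  neuron.
* KS p-values use the asymptotic two-sample formula; block sizes in
  practice are tens to hundreds of pairs.
* Ties in argmax selections (steepest trial, onset/offset) resolve to the
  earliest candidate; nearest-neighbour distance ties to the first class
  level — everything is deterministic given the seed.
* The last ITI runs to the final tracked timestamp; prospective labels
  exclude it.

## Problem sizes used by the test and acceptance suites

Simulated checks use sessions of 16-45 trials and 12-14 neurons, ITI
means scaled to 16-20 s (post-correct) and 10-12 s (post-error) except
where the 79.1/48.4 s condition itself is under test, and 20-100 shuffle
repeats instead of the 1000-shuffle production default. These sizes keep
the full validation suite within a coffee break on one core while leaving
every effect several standard errors clear of its threshold; the
production defaults remain the documented ones.

## Known limitations

* The ISI-shuffle null cannot remove reliability-driven (attenuation)
  duration bias, only count-driven and floor effects; see the null-model
  section. Interpret residual block differences accordingly.
* The change-point sweep reports at most one onset and one offset per
  session; multi-phase expression of an ensemble is out of scope.
* The reward-site/return-trip split assumes a single contiguous visit to
  the reward zone per ITI when it clips intervals (re-entry spans are
  bridged).
* Decoding assumes binary features and a fixed linearised return path;
  continuous position decoding and nonlinear decoders are out of scope.
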