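# ensemblerecall

Analysis of neural ensemble co-activity during the inter-trial intervals
(ITIs) of Y-maze rule-learning sessions: does a population of
simultaneously recorded prefrontal neurons re-express the same pattern of
pairwise co-activity after rewarded trials, when does that recall switch
on and off within a session, and what does the population encode about
the just-finished (or upcoming) trial?

The package is for systems neuroscientists analysing tetrode or probe
recordings from maze tasks with self-paced return periods, and for anyone
who wants a tested, synthetic-data-validated implementation of this
family of co-activity statistics.

## The statistics

For the core population (the *N* neurons active in every ITI), each spike
train is convolved with a Gaussian (width sigma, default 100 ms), and
z-scored with mean and SD pooled over all ITIs. ITI *t*'s co-activity is
the matrix **S**_t of rectified correlations between the normalised
densities of every neuron pair (negative correlations are set to zero so
that co-activation is distinguished from co-suppression). Recall between
ITIs *t* and *u* is

> R(t, u) = max(0, corr(upper-triangle of **S**_t, upper-triangle of **S**_u))

giving a T x T recall matrix **R**. Because post-correct ITIs are much
longer than post-error ITIs (the animal lingers at the reward port), a
duration null is built by re-ordering each train's inter-spike intervals
within each ITI and averaging the recall matrices of (by default) 1000
such surrogates; the residual matrix **R̃** = **R** − **R̂** is used for
all comparisons. Post-correct vs post-error (or arm, cue, next-outcome,
path-length) blocks are compared with a two-sample Kolmogorov–Smirnov
test and the block-mean difference delta. A sweep over dividing ITIs
locates the onset and offset of the recalled pattern; leave-one-out
cross-validated linear decoders with shuffled-label chance quantify
position-dependent encoding of retrospective and prospective task
features; and a cross-session permutation test asks whether the learning
sessions' recall differences could be a chance subset.

A fully seeded synthetic-session generator (behaviour with an abrupt
learning transition, outcome-dependent gamma ITI durations, maze-skeleton
tracking, inhomogeneous-Poisson spiking with a reinforcement-gated
ensemble co-fluctuation) provides ground truth for every stage.

## Worked example

```r
library(ensemblerecall)

cfg <- synth_config(n_neurons = 14, n_trials = 24, learning_trial = 10,
                    p_correct_before = 0.15, p_correct_after = 0.95,
                    coupling = 1.5, ensemble_members = 1:6,
                    ensemble_window = c(10, 24),
                    mean_iti_correct_s = 16, mean_iti_error_s = 10,
                    return_time_s = 6, seed = 11)
session <- generate_session(cfg)
session
#> maze_session: 14 neurons, 24 trials, 24 ITIs, rule go_right (direction)
#>   18/24 correct; ITIs 7.0-25.4 s; 415 s of tracking

classify_session(session$trials)$label
#> [1] "learning"

R    <- recall_matrix(session, sigma = 0.1, dt = 0.02)
Rhat <- expected_recall_matrix(session, sigma = 0.1, dt = 0.02,
                               n_shuffles = 100, seed = 11)
resid <- residual_recall(R, Rhat)

block_compare(resid, label_itis(session, "prior_outcome"))
#> block comparison (offdiag): delta = 0.4881 (correct 0.5573 vs error
#>   0.0692); KS D = 0.686, p = 5.16e-06

detect_onset_offset(resid)
#> recall onset at trial 11 (D+ = 1.000, p = 0); offset at NA ...
```

Reading the output: residual recall between pairs of post-correct ITIs
averages 0.56 against 0.07 for post-error pairs — the ensemble pattern
planted in neurons 1–6 from trial 10 onward is recalled selectively after
reinforcement (delta = 0.49, KS p ≈ 5e-6) — and the onset sweep locates
its appearance at trial 11, one trial after the configured behavioural
step; no offset is reported because the pattern stays on to the session
end. `run_session()` / `run_cohort()` chain all stages (behaviour,
recall, change point, trial-vs-ITI similarity, decoding) and write JSON
reports.

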