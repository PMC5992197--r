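# Builders for small deterministic fixtures used across test files.

# a tiny hand-built session: 3 neurons, 3 trials, regular spiking
toy_session <- function() {
  trials <- data.frame(
    trial = 1:3,
    t_start_s = c(1, 10, 20), t_end_s = c(4, 13, 23),
    arm = c("right", "left", "right"), cue = c("left", "right", "right"),
    outcome = c("correct", "error", "correct"), rule = "go_right")
  tracking <- data.frame(time_s = seq(0, 30, by = 1 / 30))
  tracking$x_cm <- sin(tracking$time_s) * 10
  tracking$y_cm <- cos(tracking$time_s) * 10
  spikes <- list(
    "1" = seq(0.05, 29.9, by = 0.11),
    "2" = seq(0.07, 29.8, by = 0.17),
    "3" = seq(0.02, 29.95, by = 0.23))
  new_session(spikes, trials, tracking)
}

# fast small synthetic config: short ITIs keep density grids small
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_neurons = 12, n_trials = 16,
                   mean_iti_correct_s = 16, mean_iti_error_s = 10,
                   return_time_s = 6, seed = 1L)
  args <- utils::modifyList(defaults, args, keep.null = TRUE)
  if (!"learning_trial" %in% names(args))
    args$learning_trial <- ceiling(args$n_trials / 2)
  do.call(synth_config, args)
}

# build a session directly from per-neuron spike-time vectors over a
# regular trial grid (trial_dur, iti_dur) -- for controlled recall tests
session_from_trains <- function(spikes, n_trials = 4, trial_dur = 2,
                                iti_dur = 8, outcome = NULL) {
  step <- trial_dur + iti_dur
  t_start <- (seq_len(n_trials) - 1) * step
  if (is.null(outcome))
    outcome <- rep(c("correct", "error"), length.out = n_trials)
  trials <- data.frame(trial = seq_len(n_trials), t_start_s = t_start,
                       t_end_s = t_start + trial_dur,
                       arm = rep("right", n_trials),
                       cue = rep("left", n_trials),
                       outcome = outcome, rule = "go_right")
  t_end <- n_trials * step
  tracking <- data.frame(time_s = seq(0, t_end, by = 1 / 30),
                         x_cm = 0, y_cm = 0)
  tracking$x_cm <- tracking$time_s %% 5
  new_session(spikes, trials, tracking)
}

# Poisson train on [0, t_end) at rate hz (seeded by caller)
poisson_train <- function(hz, t_end) {
  n <- rpois(1, hz * t_end)
  unique(sort(round(runif(n, 0, t_end), 4)))
}
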