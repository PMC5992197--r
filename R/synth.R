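#' Configuration for synthetic session generation
#'
#' The generator emulates a single Y-maze training session: an abrupt
#' behavioural transition at a configurable learning trial; inter-trial
#' intervals (ITIs) that are longer after correct than after error trials
#' because the animal lingers at the reward port (defaults 79.1 s vs
#' 48.4 s, gamma-distributed with shape 4); a population of Poisson neurons
#' of which a configurable subset shares a reinforcement-gated latent rate
#' co-fluctuation at the ~100 ms timescale, expressed only during ITIs that
#' follow a correct trial and fall inside \code{ensemble_window}; and
#' optional position-dependent rate tuning to retrospective task features.
#'
#' @param n_neurons number of units (study range 15-55; default 25).
#' @param n_trials number of trials (default 40).
#' @param learning_trial index L of the behavioural transition, or NA for a
#'   stationary session; outcomes are Bernoulli(\code{p_correct_before})
#'   for trials < L and Bernoulli(\code{p_correct_after}) from L on.
#' @param p_correct_before,p_correct_after success probabilities.
#' @param mean_iti_correct_s,mean_iti_error_s mean ITI durations by prior
#'   outcome, seconds.
#' @param iti_shape gamma shape for ITI durations (default 4).
#' @param rule one of "go_right", "go_cued", "go_left", "go_uncued".
#' @param base_rates_hz per-neuron baseline rates; NULL draws them
#'   uniformly from 2-8 Hz.
#' @param ensemble_members integer indices of the coupled subset (default:
#'   first third of the population).
#' @param coupling dimensionless coupling strength c >= 0; the shared
#'   latent z(t) (unit-variance Ornstein-Uhlenbeck, 100 ms correlation
#'   time) scales rates as exp(c*z - c^2/2) during gated ITIs.
#' @param ensemble_window \code{c(onset_trial, offset_trial)}: trials whose
#'   post-correct ITIs express the ensemble (default the whole session).
#' @param background_coupling strength of an outcome-independent latent
#'   co-fluctuation (same 100 ms timescale, heterogeneous per-neuron
#'   weights) shared by all neurons in every ITI, emulating the noise
#'   correlations cortical populations always carry regardless of
#'   reinforcement (default 0.4, giving mean raw recall values of order
#'   0.1 between intervals).
#' @param tuning_spec NULL or data frame with columns \code{feature}
#'   ("prior_outcome", "prior_arm" or "prior_cue"), \code{section} (1..5)
#'   and \code{multiplier}: during ITI t, the rates of
#'   \code{tuned_neurons} are multiplied by \code{multiplier} whenever the
#'   animal occupies that maze section and trial t has the feature's
#'   reference level (correct / right / right).
#' @param tuned_neurons indices receiving the tuning multipliers.
#' @param section_profiles per-neuron spatial rate profiles: an
#'   \code{n_neurons x 5} matrix of multipliers applied by occupied maze
#'   section (outcome-independent, identical in every interval), emulating
#'   the broad position dependence of prefrontal firing. The default
#'   "random" draws log-normal profiles (sdlog \code{profile_sd}) once per
#'   session; NULL disables spatial structure entirely.
#' @param profile_sd sdlog of the random section profiles (default 0.4).
#' @param trial_dur_s mean trial duration (default 4 s).
#' @param return_time_s time spent on the return run within each ITI; the
#'   remainder is spent at the reward site (default 15 s).
#' @param stationary if TRUE the animal never leaves the goal-arm end
#'   during ITIs (zero path length).
#' @param jitter_cm sd of Gaussian positional jitter added to tracking.
#' @param ou_tau_s correlation time of the shared latent (default 0.1 s).
#' @param dt_gen_s rate-grid resolution for spike generation (default 5 ms).
#' @param seed master integer seed; all stages derive their own streams.
#' @return a validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_neurons = 25, n_trials = 40,
                         learning_trial = ceiling(n_trials / 2),
                         p_correct_before = 0.2, p_correct_after = 0.9,
                         mean_iti_correct_s = 79.1, mean_iti_error_s = 48.4,
                         iti_shape = 4, rule = "go_right",
                         base_rates_hz = NULL,
                         ensemble_members = seq_len(max(1, floor(n_neurons / 3))),
                         coupling = 0, background_coupling = 0.4,
                         ensemble_window = c(1, n_trials),
                         tuning_spec = NULL, tuned_neurons = integer(0),
                         section_profiles = "random", profile_sd = 0.4,
                         trial_dur_s = 4, return_time_s = 15,
                         stationary = FALSE, jitter_cm = 0,
                         ou_tau_s = 0.1, dt_gen_s = 0.005, seed = 1L) {
  cfg <- as.list(environment())
  if (n_neurons < 1 || n_trials < 1) stop("need >= 1 neuron and trial")
  for (p in c(p_correct_before, p_correct_after))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (!is.na(learning_trial) &&
      (learning_trial < 1 || learning_trial > n_trials))
    stop("learning_trial outside [1, n_trials]")
  if (mean_iti_correct_s <= 0 || mean_iti_error_s <= 0 || iti_shape <= 0)
    stop("ITI duration parameters must be positive")
  if (!rule %in% c("go_right", "go_cued", "go_left", "go_uncued"))
    stop("unknown rule: ", rule)
  if (is.null(base_rates_hz)) {
    cfg$base_rates_hz <- NULL  # drawn in generate_spikes from its stream
  } else {
    if (length(base_rates_hz) == 1)
      cfg$base_rates_hz <- rep(base_rates_hz, n_neurons)
    if (length(cfg$base_rates_hz) != n_neurons)
      stop("base_rates_hz must have length n_neurons")
    if (any(cfg$base_rates_hz <= 0)) stop("base rates must be positive")
  }
  if (coupling < 0 || background_coupling < 0)
    stop("coupling strengths must be >= 0")
  if (coupling > 0 && length(ensemble_members) == 0)
    stop("coupling > 0 requires a non-empty ensemble")
  if (length(ensemble_members) &&
      (min(ensemble_members) < 1 || max(ensemble_members) > n_neurons))
    stop("ensemble_members out of range")
  w <- ensemble_window
  if (length(w) != 2 || w[1] > w[2] || w[1] < 1 || w[2] > n_trials)
    stop("ensemble_window must satisfy 1 <= onset <= offset <= n_trials")
  if (is.matrix(section_profiles)) {
    if (!all(dim(section_profiles) == c(n_neurons, 5)))
      stop("section_profiles must be an n_neurons x 5 matrix")
    if (any(section_profiles <= 0)) stop("section profiles must be positive")
  } else if (!is.null(section_profiles) &&
             !identical(section_profiles, "random"))
    stop("section_profiles must be NULL, \"random\", or a matrix")
  if (!is.null(tuning_spec)) {
    need <- c("feature", "section", "multiplier")
    if (!all(need %in% names(tuning_spec)))
      stop("tuning_spec needs columns feature, section, multiplier")
    if (!all(tuning_spec$feature %in%
             c("prior_outcome", "prior_arm", "prior_cue")))
      stop("unknown feature in tuning_spec")
    if (!all(tuning_spec$section %in% 1:5))
      stop("tuning_spec sections must be 1..5")
    if (any(tuning_spec$multiplier <= 0))
      stop("tuning multipliers must be positive")
  }
  structure(cfg, class = "synth_config")
}

# deterministic per-stage seed streams below 2^31
derive_seed <- function(seed, stage) {
  offs <- c(behaviour = 11L, tracking = 23L, spikes = 37L, rates = 41L)
  (as.integer(seed) %% 1000003L) * 2011L + offs[[stage]]
}

#' Generate the behavioural trial table of a synthetic session
#'
#' Outcomes are Bernoulli with a step change at the learning trial; arms and
#' cues are drawn consistently with the configured rule (cue sides are lit
#' pseudo-randomly whether or not the rule is cue-based); trial and ITI
#' durations are gamma-distributed, ITI means conditioned on outcome.
#'
#' @param config a [synth_config()].
#' @return trial data frame in the [new_session()] schema, with attribute
#'   \code{iti_dur_s} holding the drawn ITI duration after each trial (the
#'   gap to the next trial; the last value sets the post-session tail).
#' @export
generate_behaviour <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "behaviour"))
  n <- config$n_trials
  L <- config$learning_trial
  p <- if (is.na(L)) rep(config$p_correct_before, n) else
    ifelse(seq_len(n) < L, config$p_correct_before, config$p_correct_after)
  outcome <- ifelse(rbinom(n, 1, p) == 1, "correct", "error")
  cue <- ifelse(rbinom(n, 1, 0.5) == 1, "right", "left")
  flip <- function(a) ifelse(a == "right", "left", "right")
  arm <- switch(config$rule,
    go_right = ifelse(outcome == "correct", "right", "left"),
    go_left = ifelse(outcome == "correct", "left", "right"),
    go_cued = ifelse(outcome == "correct", cue, flip(cue)),
    go_uncued = ifelse(outcome == "correct", flip(cue), cue))
  trial_dur <- rgamma(n, shape = 16, scale = config$trial_dur_s / 16)
  iti_mean <- ifelse(outcome == "correct",
                     config$mean_iti_correct_s, config$mean_iti_error_s)
  iti_dur <- rgamma(n, shape = config$iti_shape,
                    scale = iti_mean / config$iti_shape)
  # ITIs must at least accommodate the return run
  iti_dur <- pmax(iti_dur, config$return_time_s + 1)
  t_start <- 2 + c(0, cumsum(trial_dur[-n] + iti_dur[-n]))
  trials <- data.frame(trial = seq_len(n),
                       t_start_s = round(t_start, 4),
                       t_end_s = round(t_start + trial_dur, 4),
                       arm = arm, cue = cue, outcome = outcome,
                       rule = config$rule)
  attr(trials, "iti_dur_s") <- iti_dur
  trials
}

#' Generate 30 Hz tracking for a synthetic session
#'
#' The animal runs start -> choice point -> chosen goal-arm end during each
#' trial, dwells at the goal-arm end (reward site), then returns along the
#' skeleton over \code{return_time_s}. With zero jitter each ITI's path
#' length is exactly the 170 cm skeleton return path; the stationary option
#' keeps the animal at the reward site for the whole ITI.
#'
#' @param config a [synth_config()].
#' @param trials output of [generate_behaviour()].
#' @return tracking data frame (\code{time_s}, \code{x_cm}, \code{y_cm}).
#' @export
generate_tracking <- function(config, trials) {
  set.seed(derive_seed(config$seed, "tracking"))
  geo <- maze_geometry()
  n <- nrow(trials)
  iti_dur <- attr(trials, "iti_dur_s")
  if (is.null(iti_dur))
    iti_dur <- c(trials$t_start_s[-1] - trials$t_end_s[-n],
                 config$mean_iti_error_s)
  # keyframe path: (time, x, y) nodes, linearly interpolated at 30 Hz
  kt <- 0; kx <- geo$start_pos[1]; ky <- geo$start_pos[2]
  add <- function(t, p) { kt <<- c(kt, t); kx <<- c(kx, p[1]); ky <<- c(ky, p[2]) }
  for (i in seq_len(n)) {
    goal <- if (trials$arm[i] == "left") geo$goal_left else geo$goal_right
    t0 <- trials$t_start_s[i]; t1 <- trials$t_end_s[i]
    add(t0, geo$start_pos)
    add(t0 + (t1 - t0) / 2, c(0, 0))
    add(t1, goal)
    iti_end <- t1 + iti_dur[i]
    if (config$stationary) {
      add(iti_end, goal)
    } else {
      rt <- min(config$return_time_s, iti_dur[i])
      add(iti_end - rt, goal)
      add(iti_end - rt / 2, c(0, 0))
      add(iti_end, geo$start_pos)
    }
  }
  # snap keyframes to the 30 Hz grid so corner points are sampled exactly
  # (keeps the zero-jitter ITI path length at the analytic skeleton value)
  kt <- cummax(round(kt * 30) / 30)
  ts <- seq(0, max(kt), by = 1 / 30)
  x <- approx(kt, kx, xout = ts, rule = 2, ties = "ordered")$y
  y <- approx(kt, ky, xout = ts, rule = 2, ties = "ordered")$y
  if (config$jitter_cm > 0) {
    x <- x + rnorm(length(x), 0, config$jitter_cm)
    y <- y + rnorm(length(y), 0, config$jitter_cm)
  }
  data.frame(time_s = round(ts, 6), x_cm = round(x, 6), y_cm = round(y, 6))
}

#' Generate spike trains for a synthetic session
#'
#' Inhomogeneous Poisson spiking on a fine rate grid. Ensemble members share
#' a single unit-variance Ornstein-Uhlenbeck latent z(t) with 100 ms
#' correlation time; their log rates gain \code{c*z(t) - c^2/2} only during
#' ITIs that follow a correct trial and fall inside the configured ensemble
#' window, producing reinforcement-gated co-fluctuations at the ~100 ms
#' timescale. Tuning multipliers from \code{tuning_spec} are applied to
#' \code{tuned_neurons} as a function of maze section and the preceding
#' trial's features. Spike times are rounded to 0.1 ms.
#'
#' @param config a [synth_config()].
#' @param trials output of [generate_behaviour()].
#' @param tracking output of [generate_tracking()].
#' @return named list of spike-time vectors (one per neuron).
#' @export
generate_spikes <- function(config, trials, tracking) {
  if (config$coupling > 0 && length(config$ensemble_members) == 0)
    stop("coupling > 0 requires a non-empty ensemble")
  set.seed(derive_seed(config$seed, "rates"))
  rates <- config$base_rates_hz
  if (is.null(rates)) rates <- runif(config$n_neurons, 2, 8)
  prof <- config$section_profiles
  if (identical(prof, "random"))
    prof <- matrix(exp(rnorm(config$n_neurons * 5, 0, config$profile_sd)),
                   config$n_neurons, 5)

  set.seed(derive_seed(config$seed, "spikes"))
  dt <- config$dt_gen_s
  t_end <- max(tracking$time_s)
  grid <- seq(0, t_end, by = dt)      # bin start times
  nb <- length(grid)
  n <- nrow(trials)
  iti <- build_itis(trials, t_end)

  # shared OU latent, unit marginal variance, correlation time ou_tau_s
  a <- exp(-dt / config$ou_tau_s)
  z <- as.numeric(stats::filter(rnorm(nb, 0, sqrt(1 - a^2)), a,
                                method = "recursive", init = rnorm(1)))

  # per-bin context: which ITI (0 = none), and gated-ensemble mask
  bin_iti <- rep(0L, nb)
  for (t in seq_len(n)) {
    idx <- which(grid >= iti$t_start_s[t] & grid < iti$t_end_s[t])
    bin_iti[idx] <- t
  }
  w <- config$ensemble_window
  gated_tr <- which(trials$outcome == "correct" &
                    seq_len(n) >= w[1] & seq_len(n) <= w[2])
  gate <- bin_iti %in% gated_tr

  sec <- NULL
  if (!is.null(prof) ||
      (!is.null(config$tuning_spec) && length(config$tuned_neurons)))
    sec <- bin_sections(trials, tracking, grid, bin_iti)

  # per-bin tuning multiplier (only for tuned_neurons)
  tune_mult <- rep(1, nb)
  if (!is.null(config$tuning_spec) && length(config$tuned_neurons)) {
    ref <- c(prior_outcome = "correct", prior_arm = "right",
             prior_cue = "right")
    col <- c(prior_outcome = "outcome", prior_arm = "arm", prior_cue = "cue")
    ts <- config$tuning_spec
    for (r in seq_len(nrow(ts))) {
      feat <- ts$feature[r]
      on_tr <- which(trials[[col[[feat]]]] == ref[[feat]])
      hit <- bin_iti %in% on_tr & !is.na(sec) & sec == ts$section[r]
      tune_mult[hit] <- tune_mult[hit] * ts$multiplier[r]
    }
  }

  c_ <- config$coupling
  c0 <- config$background_coupling
  mod <- if (c_ > 0) exp(c_ * z - c_^2 / 2) else rep(1, nb)
  if (c0 > 0) {
    z0 <- as.numeric(stats::filter(rnorm(nb, 0, sqrt(1 - a^2)), a,
                                   method = "recursive", init = rnorm(1)))
    # per-neuron weights spread the background correlation across pairs
    w0 <- runif(config$n_neurons, 0.25, 1)
    in_iti <- bin_iti > 0
  }
  spikes <- vector("list", config$n_neurons)
  in_sec <- if (is.null(sec)) NULL else which(!is.na(sec))
  for (k in seq_len(config$n_neurons)) {
    lam <- rep(rates[k], nb)
    if (c_ > 0 && k %in% config$ensemble_members)
      lam[gate] <- lam[gate] * mod[gate]
    if (c0 > 0) {
      ck <- c0 * w0[k]
      lam[in_iti] <- lam[in_iti] * exp(ck * z0[in_iti] - ck^2 / 2)
    }
    if (!is.null(prof))
      lam[in_sec] <- lam[in_sec] * prof[k, sec[in_sec]]
    if (k %in% config$tuned_neurons) lam <- lam * tune_mult
    counts <- rpois(nb, lam * dt)
    tot <- sum(counts)
    if (tot == 0) { spikes[[k]] <- numeric(0); next }
    st <- rep(grid, counts) + runif(tot) * dt
    spikes[[k]] <- unique(sort(round(st, 4)))
  }
  names(spikes) <- as.character(seq_len(config$n_neurons))
  spikes
}

# maze section of each rate-grid bin (NA outside ITIs / off-path)
bin_sections <- function(trials, tracking, grid, bin_iti) {
  geo <- maze_geometry()
  x <- approx(tracking$time_s, tracking$x_cm, xout = grid, rule = 2)$y
  y <- approx(tracking$time_s, tracking$y_cm, xout = grid, rule = 2)$y
  sec <- rep(NA_integer_, length(grid))
  for (t in unique(bin_iti[bin_iti > 0])) {
    idx <- which(bin_iti == t)
    s <- linearise_path(x[idx], y[idx], trials$arm[t], geo)
    sec[idx] <- maze_section(s, geo)
  }
  sec
}

#' Generate a complete synthetic session
#'
#' Runs [generate_behaviour()], [generate_tracking()] and
#' [generate_spikes()] under per-stage seed streams derived from the master
#' seed, and assembles a validated session. Ground truth (configured
#' learning trial, ensemble membership and window) is attached as the
#' \code{ground_truth} attribute for recovery tests.
#'
#' @param config a [synth_config()].
#' @return a \code{maze_session} with attribute \code{ground_truth}.
#' @export
generate_session <- function(config) {
  trials <- generate_behaviour(config)
  tracking <- generate_tracking(config, trials)
  spikes <- generate_spikes(config, trials, tracking)
  attr(trials, "iti_dur_s") <- NULL  # generator-internal; ITIs are derived
  s <- new_session(spikes, trials, tracking)
  attr(s, "ground_truth") <- list(
    learning_trial = config$learning_trial,
    ensemble_members = config$ensemble_members,
    ensemble_window = config$ensemble_window,
    coupling = config$coupling, config = config)
  s
}
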