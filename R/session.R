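#' Construct a maze session object
#'
#' A session bundles everything recorded in one training epoch: the spike
#' trains of all sorted units, the trial table, the 30 Hz position tracking,
#' and the inter-trial intervals (ITIs) derived from consecutive trial
#' boundaries. ITIs are the analysis window of the package: ITI \code{t} runs
#' from the end of trial \code{t} to the start of trial \code{t+1}; the last
#' ITI runs from the end of the last trial to the last tracked timestamp
#' (the recording continues through the final self-paced return). All times
#' are seconds; intervals are half-open \code{[start, end)} so boundary
#' spikes are never double-counted.
#'
#' @param spikes named list of numeric vectors, one per neuron, each a
#'   strictly increasing vector of spike times in seconds; names are neuron
#'   ids (coercible to integer).
#' @param trials data frame with columns \code{trial} (1-based index),
#'   \code{t_start_s}, \code{t_end_s}, \code{arm} ("left"/"right"),
#'   \code{cue} ("left"/"right"), \code{outcome} ("correct"/"error"),
#'   \code{rule} (one of "go_right", "go_cued", "go_left", "go_uncued").
#' @param tracking data frame with columns \code{time_s}, \code{x_cm},
#'   \code{y_cm}; timestamps increasing, nominally 30 Hz.
#'
#' @return An object of class \code{maze_session}: a list with elements
#'   \code{spikes}, \code{trials}, \code{itis} (data frame \code{iti},
#'   \code{t_start_s}, \code{t_end_s}, \code{duration_s}), \code{tracking},
#'   and the derived \code{rule_type} ("direction" or "cue").
#' @export
new_session <- function(spikes, trials, tracking) {
  validate_spikes(spikes)
  validate_trials(trials)
  validate_tracking(tracking)
  itis <- build_itis(trials, max(tracking$time_s))
  last_t <- max(max(tracking$time_s), max(trials$t_end_s),
                max(vapply(spikes, function(s) if (length(s)) max(s) else 0,
                           numeric(1))))
  s <- structure(
    list(spikes = spikes, trials = trials, itis = itis, tracking = tracking,
         rule_type = rule_type(trials$rule[1])),
    class = "maze_session")
  s
}

rule_type <- function(rule) {
  if (rule %in% c("go_right", "go_left")) "direction" else "cue"
}

n_trials <- function(session) nrow(session$trials)
n_neurons <- function(session) length(session$spikes)

#' @export
print.maze_session <- function(x, ...) {
  cat(sprintf("maze_session: %d neurons, %d trials, %d ITIs, rule %s (%s)\n",
              length(x$spikes), nrow(x$trials), nrow(x$itis),
              x$trials$rule[1], x$rule_type))
  cat(sprintf("  %d/%d correct; ITIs %.1f-%.1f s; %.0f s of tracking\n",
              sum(x$trials$outcome == "correct"), nrow(x$trials),
              min(x$itis$duration_s), max(x$itis$duration_s),
              max(x$tracking$time_s) - min(x$tracking$time_s)))
  invisible(x)
}

validate_spikes <- function(spikes) {
  if (!is.list(spikes) || length(spikes) == 0L)
    stop("session must contain at least one spike train")
  if (is.null(names(spikes)) || anyNA(suppressWarnings(as.integer(names(spikes)))))
    stop("spike trains must be named by integer neuron ids")
  for (id in names(spikes)) {
    t <- spikes[[id]]
    if (!is.numeric(t)) stop("spike times must be numeric (neuron ", id, ")")
    if (any(t < 0)) stop("negative spike time for neuron ", id)
    if (length(t) > 1 && any(diff(t) <= 0))
      stop("spike times not strictly increasing for neuron ", id)
  }
  invisible(TRUE)
}

validate_trials <- function(trials) {
  need <- c("trial", "t_start_s", "t_end_s", "arm", "cue", "outcome", "rule")
  if (!all(need %in% names(trials)))
    stop("trial table missing columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  if (nrow(trials) == 0L) stop("trial table is empty")
  if (!identical(trials$trial, seq_len(nrow(trials))))
    stop("trial indices must be 1..n in order")
  if (any(trials$t_start_s >= trials$t_end_s))
    stop("trial with t_start_s >= t_end_s")
  if (nrow(trials) > 1 &&
      any(trials$t_start_s[-1] < trials$t_end_s[-nrow(trials)]))
    stop("overlapping or unordered trials")
  chk <- function(col, lv) {
    if (!all(trials[[col]] %in% lv))
      stop("invalid value in column '", col, "'")
  }
  chk("arm", c("left", "right")); chk("cue", c("left", "right"))
  chk("outcome", c("correct", "error"))
  chk("rule", c("go_right", "go_cued", "go_left", "go_uncued"))
  invisible(TRUE)
}

validate_tracking <- function(tracking) {
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(tracking)))
    stop("tracking table missing columns: ",
         paste(setdiff(need, names(tracking)), collapse = ", "))
  if (nrow(tracking) < 2L) stop("tracking needs at least two samples")
  if (any(diff(tracking$time_s) <= 0))
    stop("tracking timestamps must be increasing")
  invisible(TRUE)
}

# ITI t: [end of trial t, start of trial t+1); last ITI ends at session end.
build_itis <- function(trials, session_end) {
  n <- nrow(trials)
  t_start <- trials$t_end_s
  t_end <- c(trials$t_start_s[-1], max(session_end, trials$t_end_s[n]))
  if (t_end[n] <= t_start[n]) {
    # no tracking beyond the last trial: give the last ITI zero extent is
    # invalid, so drop it from analysis by flagging a tiny positive span
    stop("session ends before the last trial does; extend tracking")
  }
  data.frame(iti = seq_len(n), t_start_s = t_start, t_end_s = t_end,
             duration_s = t_end - t_start)
}

#' Read a session from its three delimited files
#'
#' Expects the on-disk schema written by [write_session()]: \code{spikes.csv}
#' (\code{neuron_id,time_s}), \code{events.csv}
#' (\code{trial,t_start_s,t_end_s,arm,cue,outcome,rule}) and
#' \code{tracking.csv} (\code{time_s,x_cm,y_cm}). Times are stored with
#' 0.1 ms resolution intact.
#'
#' @param spikes_path,events_path,tracking_path file paths; alternatively
#'   give \code{dir} and the default file names are used.
#' @param dir directory containing \code{spikes.csv}, \code{events.csv},
#'   \code{tracking.csv}; overrides the three path arguments when non-NULL.
#' @return a validated [new_session()] object.
#' @export
read_session <- function(spikes_path = NULL, events_path = NULL,
                         tracking_path = NULL, dir = NULL) {
  if (!is.null(dir)) {
    spikes_path <- file.path(dir, "spikes.csv")
    events_path <- file.path(dir, "events.csv")
    tracking_path <- file.path(dir, "tracking.csv")
  }
  for (p in c(spikes_path, events_path, tracking_path))
    if (!file.exists(p)) stop("file not found: ", p)
  sp <- read.csv(spikes_path, colClasses = c("integer", "numeric"))
  if (!all(c("neuron_id", "time_s") %in% names(sp)))
    stop("spikes file must have columns neuron_id,time_s: ", spikes_path)
  if (anyNA(sp)) stop("malformed row (NA) in ", spikes_path, " at line ",
                      which(!complete.cases(sp))[1] + 1L)
  spikes <- split(sp$time_s, sp$neuron_id)
  spikes <- spikes[order(as.integer(names(spikes)))]
  ev <- read.csv(events_path, stringsAsFactors = FALSE)
  if (anyNA(ev)) stop("malformed row (NA) in ", events_path, " at line ",
                      which(!complete.cases(ev))[1] + 1L)
  tr <- read.csv(tracking_path)
  if (anyNA(tr)) stop("malformed row (NA) in ", tracking_path, " at line ",
                      which(!complete.cases(tr))[1] + 1L)
  new_session(spikes, ev, tr)
}

#' Write a session to three delimited files
#'
#' Inverse of [read_session()]; lossless at 0.1 ms resolution (times are
#' written with four decimal places of seconds).
#'
#' @param session a \code{maze_session}.
#' @param out_dir directory to write into (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_session <- function(session, out_dir) {
  stopifnot(inherits(session, "maze_session"))
  if (length(session$spikes) == 0L) stop("session has no neurons")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", out_dir)
  fmt <- function(x) formatC(x, format = "f", digits = 4)
  sp <- data.frame(
    neuron_id = rep(as.integer(names(session$spikes)),
                    lengths(session$spikes)),
    time_s = fmt(unlist(session$spikes, use.names = FALSE)))
  paths <- file.path(out_dir, c("spikes.csv", "events.csv", "tracking.csv"))
  write.csv(sp, paths[1], row.names = FALSE, quote = FALSE)
  ev <- session$trials
  ev$t_start_s <- fmt(ev$t_start_s); ev$t_end_s <- fmt(ev$t_end_s)
  write.csv(ev, paths[2], row.names = FALSE, quote = FALSE)
  tr <- session$tracking
  tr$time_s <- formatC(tr$time_s, format = "f", digits = 6)
  tr$x_cm <- formatC(tr$x_cm, format = "f", digits = 6)
  tr$y_cm <- formatC(tr$y_cm, format = "f", digits = 6)
  write.csv(tr, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

# spikes of one neuron inside a half-open interval [t0, t1)
spikes_in <- function(times, t0, t1) times[times >= t0 & times < t1]
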