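#' Cumulative reward curve
#'
#' Running count of correct trials; the curve whose slope is the rate of
#' reward accumulation.
#'
#' @param trials trial data frame (needs column \code{outcome}) or a
#'   character vector of outcomes.
#' @return integer vector, one entry per trial.
#' @export
cumulative_reward <- function(trials) {
  outcome <- if (is.data.frame(trials)) trials$outcome else trials
  if (length(outcome) == 0) stop("no trials")
  cumsum(outcome == "correct")
}

#' Find the learning trial by the original criterion
#'
#' The learning trial is the first of three consecutive correct trials after
#' which performance is at least 80\% correct for the remainder of the
#' session. The 80\% window starts at the candidate trial itself
#' (\code{window_from_candidate = TRUE}, the default) or after the three
#' consecutive correct trials.
#'
#' @param trials trial data frame or outcome vector.
#' @param threshold performance criterion (default 0.8).
#' @param window_from_candidate where the performance window starts.
#' @return the learning-trial index, or \code{NA_integer_} if no trial
#'   qualifies.
#' @export
find_learning_trial_original <- function(trials, threshold = 0.8,
                                         window_from_candidate = TRUE) {
  outcome <- if (is.data.frame(trials)) trials$outcome else trials
  n <- length(outcome)
  if (n < 3) return(NA_integer_)
  correct <- outcome == "correct"
  for (i in seq_len(n - 2)) {
    if (!all(correct[i:(i + 2)])) next
    from <- if (window_from_candidate) i else min(i + 3, n)
    if (mean(correct[from:n]) >= threshold) return(i)
  }
  NA_integer_
}

# robust slope by Huber M-estimation (IRLS); an exactly linear segment
# short-circuits to OLS, which is then exact. Deterministic throughout.
robust_slope <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need >= 2 points for a slope")
  ls <- lm.fit(cbind(1, x), y)
  if (max(abs(ls$residuals)) < 1e-10 * max(1, max(abs(y))))
    return(unname(ls$coefficients[2]))
  fit <- suppressWarnings(MASS::rlm(x = cbind(1, x), y = y, maxit = 100))
  unname(coef(fit)[2])
}

#' Piecewise robust fit of the cumulative reward curve
#'
#' Fits robust (Huber M-estimator) regression lines to the cumulative
#' reward curve before and after a candidate split trial; the two slopes
#' are the rates of reward accumulation r_before and r_after. The "before"
#' segment covers trials \code{1..split_trial - 1}, the "after" segment
#' \code{split_trial..n}. An M-estimator (rather than, say, Theil-Sen) is
#' used because the split search needs the fitted slope to respond
#' smoothly to contamination of a segment by the other regime: the median
#' of pairwise slopes is flat over a range of splits around a noiseless
#' kink, which makes the steepest-trial search tie over a plateau instead
#' of localising the change.
#'
#' @param cumreward cumulative reward curve from [cumulative_reward()].
#' @param split_trial candidate change trial.
#' @param min_side minimum trials required on each side (default 5).
#' @return list of class \code{piecewise_fit}: \code{split_trial},
#'   \code{r_before}, \code{r_after}, \code{delta_slope}.
#' @export
fit_piecewise <- function(cumreward, split_trial, min_side = 5) {
  n <- length(cumreward)
  before <- seq_len(split_trial - 1)
  after <- split_trial:n
  if (length(before) < min_side)
    stop("too few trials before the split (need ", min_side, ")")
  if (length(after) < min_side)
    stop("too few trials after the split (need ", min_side, ")")
  r_b <- robust_slope(before, cumreward[before])
  r_a <- robust_slope(after, cumreward[after])
  structure(list(split_trial = split_trial, r_before = r_b, r_after = r_a,
                 delta_slope = r_a - r_b), class = "piecewise_fit")
}

#' Trial with the steepest inflection of the reward curve
#'
#' Sweeps every admissible split (at least \code{min_side} trials on each
#' side) and returns the one maximising the slope increase
#' r_after - r_before; ties break to the earliest trial.
#'
#' @inheritParams fit_piecewise
#' @return list \code{trial}, \code{delta_slope}, and \code{fits} (the per-
#'   split delta slopes).
#' @export
find_steepest_trial <- function(cumreward, min_side = 5) {
  n <- length(cumreward)
  cand <- seq(min_side + 1, n - min_side + 1)
  if (length(cand) == 0 || n < 2 * min_side + 1)
    stop("too few trials for a piecewise sweep (need ", 2 * min_side + 1, ")")
  ds <- vapply(cand, function(k)
    fit_piecewise(cumreward, k, min_side)$delta_slope, numeric(1))
  best <- cand[which.max(ds)]
  list(trial = best, delta_slope = max(ds),
       fits = data.frame(trial = cand, delta_slope = ds))
}

#' Classify a session by its behavioural signature
#'
#' "learning" if the original three-in-a-row-plus-80\% criterion is met;
#' otherwise "minor_learning" if any admissible piecewise split shows a
#' positive slope increase; otherwise "other". Rule-change status is an
#' annotation supplied by the experimenter, not computed.
#'
#' @param trials trial data frame or outcome vector.
#' @param is_rule_change annotation flag (stored in the result).
#' @param min_side minimum trials each side for the piecewise sweep.
#' @return list of class \code{session_classification}: \code{label},
#'   \code{learning_trial}, \code{steepest_trial}, \code{delta_slope},
#'   \code{is_rule_change}.
#' @export
classify_session <- function(trials, is_rule_change = FALSE, min_side = 5) {
  outcome <- if (is.data.frame(trials)) trials$outcome else trials
  lt <- find_learning_trial_original(outcome)
  cum <- cumulative_reward(outcome)
  st <- if (length(outcome) >= 2 * min_side + 1)
    find_steepest_trial(cum, min_side) else NULL
  label <- if (!is.na(lt)) "learning"
  else if (!is.null(st) && st$delta_slope > 0) "minor_learning"
  else "other"
  structure(list(label = label, learning_trial = lt,
                 steepest_trial = if (is.null(st)) NA_integer_ else st$trial,
                 delta_slope = if (is.null(st)) NA_real_ else st$delta_slope,
                 is_rule_change = is_rule_change),
            class = "session_classification")
}

#' Distance travelled within a time interval
#'
#' Sum of frame-to-frame Euclidean distances over tracking samples falling
#' in the half-open interval \code{[start, end)}.
#'
#' @param tracking tracking data frame.
#' @param interval numeric \code{c(start, end)} in seconds.
#' @return path length in cm.
#' @export
path_length <- function(tracking, interval) {
  idx <- tracking$time_s >= interval[1] & tracking$time_s < interval[2]
  if (sum(idx) < 2) stop("fewer than 2 tracking samples in interval")
  x <- tracking$x_cm[idx]; y <- tracking$y_cm[idx]
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Path length of every ITI in a session
#'
#' @param session a \code{maze_session}.
#' @return numeric vector, one path length (cm) per ITI.
#' @export
iti_path_lengths <- function(session) {
  vapply(seq_len(nrow(session$itis)), function(t)
    path_length(session$tracking,
                c(session$itis$t_start_s[t], session$itis$t_end_s[t])),
    numeric(1))
}
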