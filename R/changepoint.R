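# signed two-sample KS distances: d_up = sup(F_x - F_y) is positive when y
# is stochastically larger than x; d_down = sup(F_y - F_x).
signed_ks <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  Fx <- ecdf(x)(pooled)
  Fy <- ecdf(y)(pooled)
  list(d_up = max(Fx - Fy), d_down = max(Fy - Fx))
}

#' Detect the onset and offset of the recalled ensemble pattern
#'
#' Sweeps every admissible dividing ITI k of a trial-ordered recall matrix,
#' comparing the within-block recall values among the earlier ITIs
#' (1..k-1) against the later ITIs (k..T). The onset is the dividing ITI
#' with the largest increase in mean recall from before to after, accepted
#' only if (a) its two-sample Kolmogorov-Smirnov test reaches p < alpha
#' and (b) the signed KS distance at that split agrees with the direction
#' of the mean change; the offset is the analogous largest decrease.
#' Selecting by the mean shift and gating by the KS test keeps the
#' sweep-wide false-positive rate near alpha and is robust to the extreme
#' empirical-CDF distances that blocks of only a few pairs produce by
#' chance (selecting on the KS distance itself lets those flukes win the
#' argmax). Onset and offset are searched independently; their ordering is
#' reported but not enforced, and no multiple-comparison correction is
#' applied across the sweep (the procedure is a localisation device, not a
#' family of hypothesis tests).
#'
#' @param R trial-ordered recall matrix (usually residual).
#' @param min_before,min_after minimum ITIs strictly before / from the
#'   dividing ITI on (defaults 3 and 5).
#' @param alpha significance level for a split to qualify (default 0.05).
#' @param counting block pair counting, as in [block_compare()].
#' @return list of class \code{onset_offset}: \code{onset_trial},
#'   \code{offset_trial} (NA when no split qualifies), \code{onset_stat},
#'   \code{offset_stat} (signed KS distances at the chosen splits),
#'   \code{onset_p}, \code{offset_p}, and the sweep table \code{sweep}
#'   (columns \code{split}, \code{d_mean}, \code{d_up}, \code{d_down},
#'   \code{ks_p}).
#' @export
detect_onset_offset <- function(R, min_before = 3, min_after = 5,
                                alpha = 0.05, counting = "offdiag") {
  T_ <- nrow(R)
  splits <- seq(min_before + 1, T_ - min_after + 1)
  if (length(splits) == 0 || T_ < min_before + min_after)
    stop("too few ITIs for any admissible split (need >= ",
         min_before + min_after, ")")
  rows <- lapply(splits, function(k) {
    before <- block_values(R, seq_len(k - 1), counting)
    after <- block_values(R, k:T_, counting)
    d <- signed_ks(before, after)
    p <- suppressWarnings(ks.test(before, after, exact = FALSE))$p.value
    data.frame(split = k, d_mean = mean(after) - mean(before),
               d_up = d$d_up, d_down = d$d_down, ks_p = p)
  })
  sw <- do.call(rbind, rows)
  # largest mean shift first (which.max ties -> earliest split), then the
  # significance and direction gates
  io <- which.max(sw$d_mean)
  if (!(sw$d_mean[io] > 0 && sw$ks_p[io] < alpha &&
        sw$d_up[io] > sw$d_down[io])) io <- NA_integer_
  io2 <- which.min(sw$d_mean)
  if (!(sw$d_mean[io2] < 0 && sw$ks_p[io2] < alpha &&
        sw$d_down[io2] > sw$d_up[io2])) io2 <- NA_integer_
  structure(list(
    onset_trial = if (is.na(io)) NA_integer_ else sw$split[io],
    offset_trial = if (is.na(io2)) NA_integer_ else sw$split[io2],
    onset_stat = if (is.na(io)) NA_real_ else sw$d_up[io],
    offset_stat = if (is.na(io2)) NA_real_ else sw$d_down[io2],
    onset_p = if (is.na(io)) NA_real_ else sw$ks_p[io],
    offset_p = if (is.na(io2)) NA_real_ else sw$ks_p[io2],
    sweep = sw), class = "onset_offset")
}

#' @export
print.onset_offset <- function(x, ...) {
  cat(sprintf(
    "recall onset at trial %s (D+ = %.3f, p = %.3g); offset at %s (D- = %.3f, p = %.3g)\n",
    x$onset_trial, x$onset_stat, x$onset_p,
    x$offset_trial, x$offset_stat, x$offset_p))
  invisible(x)
}
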