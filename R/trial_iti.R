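#' Is the ITI ensemble pattern a replay of the preceding trial's pattern?
#'
#' For each trial/ITI pair, computes the recall value R_within between the
#' trial's similarity matrix and the following ITI's similarity matrix,
#' using the joint core population (neurons active in every trial AND every
#' ITI; trials are short, so this is a subset of the ITI core population).
#' A null for two independently firing groups is built by ISI-shuffling the
#' ITI spike trains: R*_within is the mean recall against the shuffled-ITI
#' similarity matrices over \code{n_shuffles} repeats. The per-pair
#' difference Delta_within = R_within - R*_within is summarised by a
#' one-tailed sign test that it is greater than zero.
#'
#' @param session a \code{maze_session}.
#' @param sigma,dt as in [recall_matrix()].
#' @param n_shuffles shuffle repeats for the null (default 50).
#' @param seed optional integer seed.
#' @param labels optional per-ITI factor (e.g. from [label_itis()]): the
#'   sign test is then also run within each label group.
#' @return list of class \code{trial_iti_result}: per-pair \code{r_within},
#'   \code{r_within_shuffled}, \code{delta_within}, overall \code{p_sign},
#'   \code{n_pairs}, and (when labels are given) \code{by_group}.
#' @export
trial_iti_similarity <- function(session, sigma = 0.1, dt = NULL,
                                 n_shuffles = 50, seed = NULL,
                                 labels = NULL) {
  if (is.null(dt)) dt <- min(0.01, sigma / 5)
  if (!is.null(seed)) set.seed(seed)
  tt <- session$trials
  itis <- session$itis
  n <- nrow(itis)
  # joint core population: active in every trial and every ITI
  active_all <- function(iv_start, iv_end) {
    vapply(session$spikes, function(tr)
      all(vapply(seq_along(iv_start), function(i)
        any(tr >= iv_start[i] & tr < iv_end[i]), logical(1))), logical(1))
  }
  core <- which(active_all(c(tt$t_start_s, itis$t_start_s),
                           c(tt$t_end_s, itis$t_end_s)))
  if (length(core) < 3)
    stop("joint trial+ITI core population too small (< 3 neurons)")
  trains <- session$spikes[core]
  # session-wide normalisation pooled over every trial and ITI
  all_iv <- rbind(data.frame(a = tt$t_start_s, b = tt$t_end_s),
                  data.frame(a = itis$t_start_s, b = itis$t_end_s))
  dens_all <- lapply(seq_len(nrow(all_iv)), function(i)
    density_matrix(trains, c(all_iv$a[i], all_iv$b[i]), sigma, dt))
  ntot <- sum(vapply(dens_all, nrow, integer(1)))
  mu <- Reduce(`+`, lapply(dens_all, colSums)) / ntot
  s2 <- Reduce(`+`, lapply(dens_all, function(m) colSums(m * m)))
  sdv <- sqrt(pmax(0, (s2 - ntot * mu^2) / (ntot - 1)))
  if (any(sdv == 0))
    stop("zero pooled variance for neuron(s): ",
         paste(which(sdv == 0), collapse = ", "))
  zsc <- function(D) (D - rep(mu, each = nrow(D))) / rep(sdv, each = nrow(D))
  r_w <- r_sh <- numeric(n)
  for (t in seq_len(n)) {
    iti_iv <- c(itis$t_start_s[t], itis$t_end_s[t])
    S_trial <- similarity_matrix(zsc(dens_all[[t]]))
    S_iti <- similarity_matrix(zsc(dens_all[[n + t]]))
    r_w[t] <- suppressWarnings(recall_value(S_trial, S_iti))
    acc <- 0
    for (s in seq_len(n_shuffles)) {
      sh <- lapply(trains, shuffle_isi, interval = iti_iv)
      S_star <- similarity_matrix(zsc(density_matrix(sh, iti_iv, sigma, dt)))
      acc <- acc + suppressWarnings(recall_value(S_trial, S_star))
    }
    r_sh[t] <- acc / n_shuffles
  }
  d <- r_w - r_sh
  sign_p <- function(v) {
    v <- v[v != 0]
    if (!length(v)) return(1)
    binom.test(sum(v > 0), length(v), alternative = "greater")$p.value
  }
  by_group <- NULL
  if (!is.null(labels)) {
    by_group <- lapply(split(d, labels), sign_p)
  }
  structure(list(r_within = r_w, r_within_shuffled = r_sh,
                 delta_within = d, p_sign = sign_p(d), n_pairs = n,
                 core = core, by_group = by_group),
            class = "trial_iti_result")
}
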