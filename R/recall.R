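#' Core population of a session
#'
#' The fixed basis for all similarity comparisons: the neurons active (at
#' least \code{min_spikes} spikes) in every inter-trial interval of the
#' session. Using a fixed population keeps the similarity matrices of all
#' ITIs the same size, which the recall statistic requires.
#'
#' @param session a \code{maze_session}.
#' @param min_spikes activity threshold per ITI (default 1).
#' @return integer vector of neuron positions in \code{session$spikes},
#'   named by neuron id; empty (with a warning) if no neuron qualifies.
#' @export
core_population <- function(session, min_spikes = 1) {
  itis <- session$itis
  if (nrow(itis) < 1) stop("session has no ITIs")
  active <- vapply(session$spikes, function(tr) {
    all(vapply(seq_len(nrow(itis)), function(t)
      sum(tr >= itis$t_start_s[t] & tr < itis$t_end_s[t]) >= min_spikes,
      logical(1)))
  }, logical(1))
  idx <- which(active)
  if (length(idx) == 0) warning("core population is empty")
  idx
}

#' Gaussian spike-density function on a uniform grid
#'
#' Sum of Gaussian kernels (width \code{sigma}) centred on the neuron's
#' spikes inside the half-open interval, evaluated analytically at grid
#' points \code{start + (0:(n-1))*dt}. Kernels are truncated at the
#' interval edges (no padding). A single spike therefore peaks at
#' \code{1/(sigma*sqrt(2*pi))} at its own time.
#'
#' @param train numeric vector of spike times, seconds.
#' @param interval numeric \code{c(start, end)}, seconds.
#' @param sigma Gaussian width, seconds (supported range ~0.02-0.24).
#' @param dt grid step, seconds; must satisfy \code{dt <= sigma/5}.
#' @return list: \code{sample_times}, \code{values}, \code{sigma}.
#' @export
spike_density <- function(train, interval, sigma, dt) {
  if (sigma <= 0) stop("sigma must be positive")
  if (dt > sigma / 5 + 1e-12) stop("dt must be <= sigma/5")
  n <- max(2L, as.integer(floor((interval[2] - interval[1]) / dt)))
  sp <- spikes_in(train, interval[1], interval[2])
  v <- .gauss_density_cpp(sp, interval[1], n, dt, sigma)
  list(sample_times = interval[1] + (seq_len(n) - 1) * dt, values = v,
       sigma = sigma)
}

# density matrix (samples x neurons) for one interval
density_matrix <- function(trains, interval, sigma, dt) {
  n <- max(2L, as.integer(floor((interval[2] - interval[1]) / dt)))
  vapply(trains, function(tr)
    .gauss_density_cpp(spikes_in(tr, interval[1], interval[2]),
                       interval[1], n, dt, sigma),
    numeric(n))
}

#' Z-score spike densities over all ITIs of a session
#'
#' Normalises each neuron's density samples by the mean and standard
#' deviation pooled across all ITIs, giving unit-variance normalised
#' density functions. This normalisation is load-bearing: the similarity
#' between two neurons within one interval is the uncentered (cosine)
#' correlation of their normalised densities, so a neuron's deviation of
#' interval-mean rate from its session mean contributes to similarity.
#' Those deviations shrink with interval duration (count noise), which is
#' precisely the duration bias the ISI-shuffle expected recall matrix
#' reproduces and [residual_recall()] removes.
#'
#' @param densities list over ITIs of numeric matrices
#'   (samples x neurons), as built by [spike_density()] per neuron.
#' @return list of the same shape, z-scored; attribute \code{mean} and
#'   \code{sd} hold the pooled per-neuron statistics.
#' @export
zscore_over_itis <- function(densities) {
  stopifnot(is.list(densities), length(densities) >= 1)
  pooled <- do.call(rbind, densities)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop("zero pooled variance for neuron(s): ",
         paste(colnames(pooled)[bad] %||% bad, collapse = ", "))
  out <- lapply(densities, function(m) sweep(sweep(m, 2, mu), 2, sdv, "/"))
  attr(out, "mean") <- mu
  attr(out, "sd") <- sdv
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise co-activity similarity matrix for one interval
#'
#' Entry (i, j) is the rectified correlation coefficient between neurons i
#' and j's session-normalised density samples within the interval:
#' positive values are retained, negatives set to zero, so each entry lies
#' in [0, 1] (0 = never co-active, 1 = identically co-active). The inputs
#' are already centred session-wide ([zscore_over_itis()]), so the
#' coefficient is the uncentered (cosine) correlation within the interval
#' and deliberately keeps each neuron's interval-mean offset from its
#' session mean. A neuron with an all-zero norm in the interval
#' contributes zero entries (including its diagonal), keeping the matrix
#' dimension fixed across intervals.
#'
#' @param dens numeric matrix, samples x neurons (>= 2 neurons), of
#'   session-normalised densities.
#' @return symmetric N x N matrix in [0, 1].
#' @export
similarity_matrix <- function(dens) {
  if (!is.matrix(dens) || ncol(dens) < 2)
    stop("need a density matrix with >= 2 neurons")
  if (nrow(dens) < 2) stop("need >= 2 grid samples")
  rectified_cosine(dens)
}

# rectified uncentered correlation (cosine) matrix via BLAS crossprod;
# columns with zero norm give zero rows/columns (including the diagonal)
rectified_cosine <- function(M) {
  cp <- crossprod(M)
  v <- diag(cp)
  const <- v <= 0
  v[const] <- 1
  S <- cp / sqrt(outer(v, v))
  S[S < 0] <- 0
  S[S > 1] <- 1
  if (any(const)) {
    S[const, ] <- 0
    S[, const] <- 0
  }
  diag(S) <- ifelse(const, 0, 1)
  S
}

# rectified Pearson correlation matrix via BLAS crossprod; columns with zero
# variance give zero rows/columns (including the diagonal)
rectified_cor <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  cp <- crossprod(M) - n * outer(mu, mu)
  v <- diag(cp)
  const <- v <= 0
  v[const] <- 1
  S <- cp / sqrt(outer(v, v))
  S[S < 0] <- 0
  S[S > 1] <- 1
  if (any(const)) {
    S[const, ] <- 0
    S[, const] <- 0
  }
  diag(S) <- ifelse(const, 0, 1)
  S
}

#' Recall value between two intervals' similarity matrices
#'
#' The rectified Pearson correlation between the upper-triangle vectors of
#' two similarity matrices: how similar the pattern of pairwise co-activity
#' is between the two intervals, in [0, 1].
#'
#' @param S_t,S_u similarity matrices of identical dimension (>= 3
#'   neurons, so the upper triangle has >= 3 entries).
#' @return scalar in [0, 1]; 0 (with a warning) if either upper-triangle
#'   vector is constant.
#' @export
recall_value <- function(S_t, S_u) {
  if (!all(dim(S_t) == dim(S_u))) stop("similarity matrices differ in size")
  if (nrow(S_t) < 3) stop("need >= 3 neurons for a recall value")
  ut <- upper.tri(S_t)
  a <- S_t[ut]; b <- S_u[ut]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant upper-triangle vector; recall set to 0")
    return(0)
  }
  max(0, cor(a, b))
}

# ---- internal hot path -----------------------------------------------------
# trains: list over intervals of lists of per-neuron spike vectors
# returns the raw recall matrix across the given intervals: densities ->
# session-wide z-score -> per-interval cosine similarity -> Pearson between
# upper-triangle vectors, rectified
recall_from_trains <- function(trains, intervals, sigma, dt) {
  T_ <- length(trains)
  dens <- lapply(seq_len(T_), function(t)
    density_matrix(trains[[t]],
                   c(intervals$t_start_s[t], intervals$t_end_s[t]),
                   sigma, dt))
  N <- ncol(dens[[1]])
  ntot <- sum(vapply(dens, nrow, integer(1)))
  s1 <- Reduce(`+`, lapply(dens, colSums))
  s2 <- Reduce(`+`, lapply(dens, function(m) colSums(m * m)))
  mu <- s1 / ntot
  sdv <- sqrt(pmax(0, (s2 - ntot * mu^2) / (ntot - 1)))
  if (any(sdv == 0))
    stop("zero pooled variance for neuron(s): ",
         paste(which(sdv == 0), collapse = ", "))
  U <- matrix(0, N * (N - 1) / 2, T_)
  for (t in seq_len(T_)) {
    Z <- (dens[[t]] - rep(mu, each = nrow(dens[[t]]))) /
      rep(sdv, each = nrow(dens[[t]]))
    S <- rectified_cosine(Z)
    U[, t] <- S[upper.tri(S)]
  }
  if (any(vapply(seq_len(T_), function(t) all(U[, t] == U[1, t]),
                 logical(1))))
    warning("constant co-activity vector in >= 1 interval; recall set to 0")
  R <- rectified_cor(U)
  diag(R) <- 1
  R
}

iti_trains <- function(session, core) {
  itis <- session$itis
  lapply(seq_len(nrow(itis)), function(t)
    lapply(session$spikes[core], spikes_in,
           t0 = itis$t_start_s[t], t1 = itis$t_end_s[t]))
}

#' Recall matrix of a session
#'
#' For every pair of ITIs (t, u), the recall value between their similarity
#' matrices: a T x T symmetric matrix with unit diagonal showing which
#' intervals expressed similar patterns of ensemble co-activity.
#'
#' @param session a \code{maze_session}.
#' @param sigma Gaussian width, seconds (default 0.1).
#' @param dt density grid step; default \code{min(0.01, sigma/5)}.
#' @param core core-population indices; computed if NULL.
#' @return matrix of class \code{recall_matrix} with attributes
#'   \code{variant = "raw"}, \code{sigma}, \code{core}.
#' @export
recall_matrix <- function(session, sigma = 0.1, dt = NULL, core = NULL) {
  if (is.null(dt)) dt <- min(0.01, sigma / 5)
  if (is.null(core)) core <- core_population(session)
  if (length(core) < 3) stop("core population too small (< 3 neurons)")
  R <- recall_from_trains(iti_trains(session, core), session$itis, sigma, dt)
  structure(R, class = c("recall_matrix", "matrix"), variant = "raw",
            sigma = sigma, core = core)
}

#' Shuffle a spike train's inter-spike intervals within an interval
#'
#' The duration-preserving null: spikes inside the interval keep their
#' count and their first-spike offset, but the inter-spike intervals are
#' re-ordered uniformly at random. Temporal structure is destroyed while
#' everything duration- and rate-related is preserved.
#'
#' @param train spike-time vector.
#' @param interval numeric \code{c(start, end)}.
#' @return shuffled spike-time vector (times within the interval).
#' @export
shuffle_isi <- function(train, interval) {
  sp <- spikes_in(train, interval[1], interval[2])
  n <- length(sp)
  if (n <= 2) return(sp)
  isi <- diff(sp)
  sp[1] + c(0, cumsum(sample(isi)))
}

#' Expected recall matrix from ISI-shuffled surrogates
#'
#' Averages \code{n_shuffles} recall matrices, each computed after
#' independently shuffling the inter-spike intervals of every core neuron
#' in every ITI. The average captures the recall expected from interval
#' durations and firing rates alone.
#'
#' @inheritParams recall_matrix
#' @param n_shuffles number of surrogate recall matrices (default 1000).
#' @param seed optional integer seed for the shuffles.
#' @return matrix of class \code{recall_matrix}, variant "expected".
#' @export
expected_recall_matrix <- function(session, sigma = 0.1, dt = NULL,
                                   core = NULL, n_shuffles = 1000,
                                   seed = NULL) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (is.null(dt)) dt <- min(0.01, sigma / 5)
  if (is.null(core)) core <- core_population(session)
  if (length(core) < 3) stop("core population too small (< 3 neurons)")
  if (!is.null(seed)) set.seed(seed)
  trains <- iti_trains(session, core)
  itis <- session$itis
  acc <- NULL
  for (s in seq_len(n_shuffles)) {
    sh <- lapply(seq_along(trains), function(t)
      lapply(trains[[t]], shuffle_isi,
             interval = c(itis$t_start_s[t], itis$t_end_s[t])))
    R <- recall_from_trains(sh, itis, sigma, dt)
    acc <- if (is.null(acc)) R else acc + R
  }
  structure(acc / n_shuffles, class = c("recall_matrix", "matrix"),
            variant = "expected", sigma = sigma, core = core)
}

#' Residual recall matrix
#'
#' Elementwise difference between the raw and the shuffle-expected recall
#' matrices; what remains after the duration/rate bias is factored out.
#' Values lie in [-1, 1].
#'
#' @param raw,expected recall matrices of identical dimension.
#' @return matrix of class \code{recall_matrix}, variant "residual".
#' @export
residual_recall <- function(raw, expected) {
  if (!all(dim(raw) == dim(expected))) stop("recall matrices differ in size")
  structure(unclass(raw) - unclass(expected),
            class = c("recall_matrix", "matrix"), variant = "residual",
            sigma = attr(raw, "sigma"), core = attr(raw, "core"))
}

#' Label the ITIs of a session for block comparisons
#'
#' Retrospective groupings take the label from trial t (the trial an ITI
#' follows); prospective groupings from trial t+1 (the last ITI gets NA);
#' \code{path_length} splits ITIs at the session's median path length.
#' Factor level order fixes the sign of \code{delta} in [block_compare()]:
#' correct-error, right-left, short-long.
#'
#' @param session a \code{maze_session}.
#' @param grouping one of "prior_outcome", "prior_arm", "prior_cue",
#'   "next_outcome", "next_arm", "next_cue", "path_length".
#' @return factor of length nrow(session$itis) (NA = excluded ITI).
#' @export
label_itis <- function(session, grouping) {
  groupings <- c("prior_outcome", "prior_arm", "prior_cue", "next_outcome",
                 "next_arm", "next_cue", "path_length")
  if (!grouping %in% groupings)
    stop("unknown grouping: ", grouping)
  tt <- session$trials
  idx <- session$itis$iti
  n <- nrow(tt)
  lab <- switch(grouping,
    prior_outcome = factor(tt$outcome[idx], c("correct", "error")),
    prior_arm = factor(tt$arm[idx], c("right", "left")),
    prior_cue = factor(tt$cue[idx], c("right", "left")),
    next_outcome = factor(ifelse(idx + 1 <= n, tt$outcome[pmin(idx + 1, n)],
                                 NA), c("correct", "error")),
    next_arm = factor(ifelse(idx + 1 <= n, tt$arm[pmin(idx + 1, n)], NA),
                      c("right", "left")),
    next_cue = factor(ifelse(idx + 1 <= n, tt$cue[pmin(idx + 1, n)], NA),
                      c("right", "left")),
    path_length = {
      pl <- iti_path_lengths(session)
      factor(ifelse(pl < median(pl), "short", "long"), c("short", "long"))
    })
  if (length(unique(lab[!is.na(lab)])) < 2)
    stop("degenerate grouping '", grouping, "': all ITIs share one label")
  lab
}

# within-group recall values for one block
block_values <- function(R, members, counting) {
  if (counting == "full") as.vector(unclass(R)[members, members])
  else {
    sub <- unclass(R)[members, members]
    sub[upper.tri(sub)]
  }
}

#' Compare recall between two groups of ITIs
#'
#' Collects the within-group entries of a recall matrix for each label
#' group (the two block diagonals of the reordered matrix), and summarises
#' their difference: \code{delta} = mean(block1) - mean(block2), plus a
#' two-sample Kolmogorov-Smirnov test between the two distributions.
#'
#' @param R a recall matrix (usually residual).
#' @param labels per-ITI factor from [label_itis()] (NA = exclude).
#' @param counting "offdiag" (default) uses each group's off-diagonal
#'   upper-triangle pairs; "full" uses the complete block including the
#'   diagonal, matching the k x k pair counts sometimes reported for
#'   block comparisons.
#' @return list of class \code{block_comparison}: \code{grouping} levels,
#'   \code{mean_block1}, \code{mean_block2}, \code{delta}, \code{ks_stat},
#'   \code{ks_p}, \code{n1}, \code{n2}.
#' @export
block_compare <- function(R, labels, counting = c("offdiag", "full")) {
  counting <- match.arg(counting)
  labels <- as.factor(labels)
  lv <- levels(labels)
  if (length(lv) != 2) stop("labels must have exactly two levels")
  g1 <- which(labels == lv[1]); g2 <- which(labels == lv[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs >= 2 ITIs (got ", length(g1), " and ",
         length(g2), ")")
  v1 <- block_values(R, g1, counting)
  v2 <- block_values(R, g2, counting)
  ks <- suppressWarnings(ks.test(v1, v2, exact = FALSE))
  structure(list(levels = lv, mean_block1 = mean(v1), mean_block2 = mean(v2),
                 delta = mean(v1) - mean(v2),
                 ks_stat = unname(ks$statistic), ks_p = ks$p.value,
                 n1 = length(v1), n2 = length(v2), counting = counting),
            class = "block_comparison")
}

#' @export
print.block_comparison <- function(x, ...) {
  cat(sprintf(
    "block comparison (%s): delta = %.4f (%s %.4f vs %s %.4f); KS D = %.3f, p = %.3g\n",
    x$counting, x$delta, x$levels[1], x$mean_block1, x$levels[2],
    x$mean_block2, x$ks_stat, x$ks_p))
  invisible(x)
}

#' Cross-session permutation test for systematic recall
#'
#' Tests how likely it is that a designated subset of sessions (e.g. all
#' learning sessions) would all show positive recall difference by chance:
#' repeatedly draws subsets of the same size without replacement and counts
#' the fraction of draws in which every drawn session has delta > 0. The
#' analytic value is hypergeometric, C(k, m)/C(n, m) for k positive
#' sessions out of n with draw size m.
#'
#' @param deltas per-session recall differences.
#' @param target_ids indices of the designated subset (its length sets the
#'   draw size), or a single integer draw size.
#' @param n_perm number of random draws (default 10000).
#' @param seed optional integer seed.
#' @return the permutation p-value.
#' @export
session_permutation_test <- function(deltas, target_ids, n_perm = 10000,
                                     seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  m <- if (length(target_ids) == 1 && target_ids == floor(target_ids) &&
           is.null(names(target_ids))) as.integer(target_ids)
       else length(target_ids)
  n <- length(deltas)
  if (m > n) stop("draw size exceeds number of sessions")
  if (!is.null(seed)) set.seed(seed)
  pos <- deltas > 0
  hits <- vapply(seq_len(n_perm), function(i) all(pos[sample.int(n, m)]),
                 logical(1))
  mean(hits)
}

#' Restrict ITIs to reward-site or return-trip activity
#'
#' Splits each ITI at the boundary of a disc around the chosen goal-arm
#' end: \code{reward_site} keeps the sub-period while the animal is within
#' \code{radius_cm} of the reward port, \code{return_trip} the sub-period
#' outside it. Each clipped ITI spans the first to the last tracking sample
#' satisfying the condition; ITIs with no qualifying samples are dropped
#' with a warning. The returned session can be fed straight back into the
#' recall pipeline.
#'
#' @param session a \code{maze_session}.
#' @param mode "reward_site" or "return_trip".
#' @param radius_cm reward-zone radius (default 10 cm).
#' @return a \code{maze_session} whose \code{itis} table holds the clipped
#'   intervals (column \code{iti} keeps the original interval index).
#' @export
split_iti_activity <- function(session, mode = c("reward_site", "return_trip"),
                               radius_cm = 10) {
  mode <- match.arg(mode)
  geo <- maze_geometry()
  tr <- session$tracking
  frame <- median(diff(tr$time_s))
  rows <- lapply(seq_len(nrow(session$itis)), function(t) {
    it <- session$itis[t, ]
    idx <- which(tr$time_s >= it$t_start_s & tr$time_s < it$t_end_s)
    if (!length(idx)) return(NULL)
    goal <- if (session$trials$arm[t] == "left") geo$goal_left
            else geo$goal_right
    d <- sqrt((tr$x_cm[idx] - goal[1])^2 + (tr$y_cm[idx] - goal[2])^2)
    keep <- if (mode == "reward_site") d <= radius_cm else d > radius_cm
    if (!any(keep)) return(NULL)
    t0 <- tr$time_s[idx[which(keep)[1]]]
    t1 <- tr$time_s[idx[tail(which(keep), 1)]] + frame
    data.frame(iti = it$iti, t_start_s = t0, t_end_s = min(t1, it$t_end_s),
               duration_s = min(t1, it$t_end_s) - t0)
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " ITI(s) without ", mode, " activity dropped")
  if (all(dropped)) stop("no ITI retains any ", mode, " activity")
  out <- session
  out$itis <- do.call(rbind, rows[!dropped])
  out
}
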