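# brute-force oracles kept deliberately naive and separate from the
# implementation paths they check
cosine_oracle <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
pearson_oracle <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

test_that("core population is the intersection of per-ITI activity", {
  s <- toy_session()  # all three neurons tonically active
  expect_equal(unname(core_population(s)), 1:3)
  sp <- s$spikes
  sp[["2"]] <- sp[["2"]][sp[["2"]] < 13 | sp[["2"]] >= 20]  # silent in ITI 2
  s2 <- new_session(sp, s$trials, s$tracking)
  expect_equal(unname(core_population(s2)), c(1, 3))
  # random activity masks vs a set-intersection oracle
  set.seed(42)
  for (rep in 1:5) {
    spikes <- lapply(1:6, function(k) {
      tr <- numeric(0)
      for (iti in 1:3)  # ITIs at [4,10), [13,20), [23,30)
        if (runif(1) < 0.7)
          tr <- c(tr, runif(3, c(4, 13, 23)[iti], c(10, 20, 29.9)[iti]))
      unique(sort(round(c(tr, runif(2, 0, 3.9)), 4)))
    })
    names(spikes) <- 1:6
    s3 <- new_session(spikes, s$trials, s$tracking)
    oracle <- which(vapply(spikes, function(tr) {
      all(vapply(1:3, function(t)
        any(tr >= s3$itis$t_start_s[t] & tr < s3$itis$t_end_s[t]),
        logical(1)))
    }, logical(1)))
    expect_equal(suppressWarnings(unname(core_population(s3))),
                 unname(oracle))
  }
  expect_warning(core_population(new_session(
    list("1" = 0.5), s$trials, s$tracking)), "empty")
})

test_that("spike density matches the closed-form Gaussian sum", {
  d0 <- spike_density(numeric(0), c(0, 2), sigma = 0.1, dt = 0.01)
  expect_true(all(d0$values == 0))
  # single spike exactly on a grid point peaks at 1/(sigma*sqrt(2*pi))
  d1 <- spike_density(1.0, c(0, 2), sigma = 0.1, dt = 0.01)
  expect_equal(max(d1$values), 1 / (0.1 * sqrt(2 * pi)), tolerance = 1e-10)
  expect_equal(d1$sample_times[which.max(d1$values)], 1.0)
  # several spikes: pointwise equality with a dnorm-sum oracle
  sp <- c(0.31, 0.32, 1.557)
  for (sigma in c(0.02, 0.1, 0.24)) {
    d <- spike_density(sp, c(0, 2), sigma = sigma, dt = sigma / 5)
    oracle <- vapply(d$sample_times,
                     function(g) sum(dnorm(g, sp, sigma)), numeric(1))
    expect_equal(d$values, oracle, tolerance = 1e-4)  # 5-sigma truncation
  }
  expect_error(spike_density(sp, c(0, 2), sigma = 0.1, dt = 0.05), "dt")
  expect_error(spike_density(sp, c(0, 2), sigma = -1, dt = 0.01), "sigma")
})

test_that("z-scoring pools over all ITIs and matches a two-pass oracle", {
  set.seed(7)
  dens <- lapply(c(50, 80, 30), function(n) matrix(rexp(n * 3), n, 3))
  z <- zscore_over_itis(dens)
  pooled <- do.call(rbind, z)
  expect_equal(colMeans(pooled), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(pooled, 2, sd), rep(1, 3), tolerance = 1e-12)
  raw <- do.call(rbind, dens)
  expect_equal(attr(z, "mean"), colMeans(raw))
  expect_equal(attr(z, "sd"), apply(raw, 2, sd))
  dens[[2]][, 2] <- 0.7  # constant in one interval is fine...
  expect_silent(zscore_over_itis(dens))
  dens <- lapply(dens, function(m) { m[, 2] <- 0.7; m })  # ...everywhere not
  expect_error(zscore_over_itis(dens), "neuron")
})

test_that("similarity is the rectified cosine of normalised densities", {
  t_ <- seq(0, 2 * pi, length.out = 100)
  z <- cbind(sin(t_), sin(t_), -sin(t_))
  S <- similarity_matrix(z)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 2], 1)          # identical signal
  expect_equal(S[1, 3], 0)          # anti-phase pair rectified to zero
  expect_true(isSymmetric(S))
  set.seed(8)
  Z <- matrix(rnorm(60), 20, 3)
  S2 <- similarity_matrix(Z)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(S2[i, j], max(0, cosine_oracle(Z[, i], Z[, j])))
})

test_that("recall value equals a hand Pearson on upper triangles", {
  S_a <- matrix(c(1, .2, .3, .4,
                  .2, 1, .5, .6,
                  .3, .5, 1, .7,
                  .4, .6, .7, 1), 4, 4)
  expect_equal(recall_value(S_a, S_a), 1)
  ut <- upper.tri(S_a)
  S_b <- S_a
  S_b[ut] <- c(.9, .1, .8, .05, .6, .2)
  S_b[lower.tri(S_b)] <- t(S_b)[lower.tri(S_b)]
  expect_equal(recall_value(S_a, S_b),
               max(0, pearson_oracle(S_a[ut], S_b[ut])))
  # anti-correlated upper triangles rectify to zero
  S_c <- S_a
  S_c[ut] <- 1 - S_a[ut]
  S_c[lower.tri(S_c)] <- t(S_c)[lower.tri(S_c)]
  expect_equal(recall_value(S_a, S_c), 0)
  expect_error(recall_value(S_a, S_a[1:3, 1:3]), "size")
  expect_warning(v <- recall_value(diag(4) * 0 + 0.5, S_a), "constant")
  expect_equal(v, 0)
})

test_that("recall value matches the oracle on many small instances", {
  set.seed(13)
  for (rep in 1:40) {
    n_g <- sample(5:20, 1)
    Z1 <- matrix(rnorm(n_g * 4), n_g, 4)
    Z2 <- matrix(rnorm(n_g * 4), n_g, 4)
    S1 <- similarity_matrix(Z1)
    S2 <- similarity_matrix(Z2)
    ut <- upper.tri(S1)
    o <- if (sd(S1[ut]) == 0 || sd(S2[ut]) == 0) 0
         else max(0, pearson_oracle(S1[ut], S2[ut]))
    expect_equal(suppressWarnings(recall_value(S1, S2)), o)
  }
})

test_that("recall matrix is symmetric, unit-diagonal, oracle-consistent", {
  set.seed(9)
  spikes <- setNames(lapply(1:4, function(k) poisson_train(6, 40)),
                     1:4)
  s <- session_from_trains(spikes, n_trials = 4, trial_dur = 2, iti_dur = 8)
  R <- recall_matrix(s, sigma = 0.1, dt = 0.02)
  expect_equal(dim(unclass(R)), c(4, 4))
  expect_true(isSymmetric(unclass(R)))
  expect_equal(diag(unclass(R)), rep(1, 4))
  expect_true(all(R >= 0 & R <= 1))
  # independent reconstruction: densities -> pooled z-score -> cosine ->
  # Pearson of upper triangles
  core <- core_population(s)
  dens <- lapply(1:4, function(t)
    vapply(s$spikes[core], function(tr) {
      iv <- c(s$itis$t_start_s[t], s$itis$t_end_s[t])
      spike_density(tr, iv, 0.1, 0.02)$values
    }, numeric(floor(s$itis$duration_s[t] / 0.02))))
  z <- zscore_over_itis(dens)
  Ss <- lapply(z, similarity_matrix)
  for (t in 1:3) for (u in (t + 1):4)
    expect_equal(R[t, u], recall_value(Ss[[t]], Ss[[u]]), tolerance = 1e-12)
})

test_that("identical activity in every ITI gives an all-ones recall matrix", {
  # same spike pattern replayed in each 8 s ITI (trials silent)
  pat <- c(0.3, 0.45, 1.2, 3.3, 5.05, 7.4)
  mk <- function(jit) unlist(lapply(0:3, function(t) 2 + t * 10 + jit + pat))
  spikes <- list("1" = mk(0), "2" = mk(0.12), "3" = mk(0.31))
  s <- session_from_trains(spikes, n_trials = 4, trial_dur = 2, iti_dur = 8)
  R <- recall_matrix(s, sigma = 0.1, dt = 0.02)
  expect_true(all(R > 0.999))
})

test_that("ISI shuffling preserves count, first offset and ISI multiset", {
  expect_equal(shuffle_isi(c(1.5), c(0, 10)), 1.5)
  expect_equal(shuffle_isi(c(1.5, 2.5), c(0, 10)), c(1.5, 2.5))
  set.seed(10)
  for (rep in 1:20) {
    tr <- poisson_train(5, 20)
    sh <- shuffle_isi(tr, c(0, 20))
    expect_equal(length(sh), length(tr))
    expect_equal(sh[1], tr[1])                      # anchored first spike
    expect_equal(sort(diff(sh)), sort(diff(tr)))    # ISI multiset
    expect_equal(max(sh), max(tr))                  # stays inside interval
    expect_true(all(sh >= 0 & sh < 20))
  }
})

test_that("expected recall matrix averages shuffled recall matrices", {
  set.seed(3)
  spikes <- setNames(lapply(1:4, function(k) poisson_train(5, 40)), 1:4)
  s <- session_from_trains(spikes, n_trials = 4)
  e1 <- expected_recall_matrix(s, sigma = 0.1, dt = 0.02, n_shuffles = 1,
                               seed = 77)
  # one shuffle equals the recall matrix of the surrogate session built
  # from the same RNG stream
  set.seed(77)
  core <- core_population(s)
  sh_spikes <- lapply(s$spikes[core], function(tr) {
    out <- numeric(0)
    for (t in 1:4) {
      iv <- c(s$itis$t_start_s[t], s$itis$t_end_s[t])
      out <- c(out, shuffle_isi(tr, iv))
    }
    out
  })
  expect_true(all(e1 >= 0 & e1 <= 1))
  e2 <- expected_recall_matrix(s, sigma = 0.1, dt = 0.02, n_shuffles = 5,
                               seed = 1)
  expect_true(isSymmetric(unclass(e2)))
  expect_error(expected_recall_matrix(s, n_shuffles = 0), "n_shuffles")
})

test_that("residual recall is the elementwise difference with bounds", {
  set.seed(4)
  A <- matrix(runif(16), 4, 4); A <- (A + t(A)) / 2; diag(A) <- 1
  B <- matrix(runif(16), 4, 4); B <- (B + t(B)) / 2; diag(B) <- 1
  res <- residual_recall(A, B)
  expect_equal(unclass(res), A - B, ignore_attr = TRUE)
  expect_true(all(res >= -1 & res <= 1))
  expect_equal(unclass(residual_recall(A, A)), matrix(0, 4, 4),
               ignore_attr = TRUE)
  expect_error(residual_recall(A, B[1:3, 1:3]), "size")
})

test_that("block comparison summarises within-group pairs correctly", {
  # construct a 6-ITI residual matrix with exact block values
  lab <- factor(c("correct", "correct", "correct", "error", "error",
                  "error"), c("correct", "error"))
  M <- matrix(NA_real_, 6, 6)
  M[1:3, 1:3] <- 0.5; M[4:6, 4:6] <- 0.1
  M[1:3, 4:6] <- 0.3; M[4:6, 1:3] <- 0.3
  diag(M) <- 1
  bc <- block_compare(M, lab)
  expect_equal(bc$delta, 0.4)
  expect_equal(bc$ks_stat, 1)
  expect_equal(bc$n1, 3)  # 3 off-diagonal upper-triangle pairs per group
  full <- block_compare(M, lab, counting = "full")
  expect_equal(full$n1, 9)
  expect_equal(full$mean_block1, (0.5 * 6 + 3) / 9)
  # same-distribution blocks: delta 0 and high KS p
  M2 <- M; M2[1:3, 1:3] <- 0.1
  expect_equal(block_compare(M2, lab)$delta, 0)
  expect_error(block_compare(M, factor(c("a", "a", "a", "a", "a", "b"))),
               ">= 2")
})

test_that("KS statistic equals the brute-force ECDF maximum", {
  set.seed(14)
  for (rep in 1:10) {
    lab <- factor(rep(c("correct", "error"), times = c(4, 5)),
                  c("correct", "error"))
    M <- matrix(runif(81), 9, 9); M <- (M + t(M)) / 2; diag(M) <- 1
    bc <- block_compare(M, lab)
    g1 <- M[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
    g2 <- M[5:9, 5:9][upper.tri(matrix(0, 5, 5))]
    grid <- sort(c(g1, g2))
    oracle <- max(abs(vapply(grid, function(x)
      mean(g1 <= x) - mean(g2 <= x), numeric(1))))
    expect_equal(bc$ks_stat, oracle)
  }
})

test_that("ITI labelling follows trial structure and median path split", {
  s <- toy_session()  # outcomes C, E, C
  expect_equal(as.character(label_itis(s, "prior_outcome")),
               c("correct", "error", "correct"))
  nx <- label_itis(s, "next_outcome")
  expect_equal(as.character(nx), c("error", "correct", NA))
  expect_error(label_itis(s, "bogus"), "unknown grouping")
  # degenerate grouping errors
  s_all <- s
  s_all$trials$outcome <- "correct"
  expect_error(label_itis(s_all, "prior_outcome"), "degenerate")
  # path-length split sizes differ by at most 1
  set.seed(15)
  cfgs <- quick_cfg(n_neurons = 3, n_trials = 9, jitter_cm = 0.5)
  ss <- generate_session(cfgs)
  pl <- label_itis(ss, "path_length")
  expect_lte(abs(sum(pl == "short") - sum(pl == "long")), 1)
})

test_that("session permutation test matches the hypergeometric formula", {
  expect_equal(session_permutation_test(rep(1, 8), 1:3, n_perm = 200,
                                        seed = 1), 1)
  expect_equal(session_permutation_test(c(1, 1, -1, -1), 1:3,
                                        n_perm = 200, seed = 1), 0)
  grid <- list(c(n = 10, k = 6, m = 3), c(n = 12, k = 8, m = 4),
               c(n = 9, k = 7, m = 2), c(n = 8, k = 5, m = 5))
  for (g in grid) {
    deltas <- c(rep(1, g["k"]), rep(-1, g["n"] - g["k"]))
    n_perm <- 4000
    p_mc <- session_permutation_test(deltas, seq_len(g["m"]),
                                     n_perm = n_perm, seed = 2)
    p_true <- choose(g["k"], g["m"]) / choose(g["n"], g["m"])
    se <- sqrt(p_true * (1 - p_true) / n_perm)
    expect_lt(abs(p_mc - p_true), 3 * se + 1e-12)
  }
  expect_error(session_permutation_test(1:3, 1:2, n_perm = 0), "n_perm")
  expect_error(session_permutation_test(1:3, 1:5), "draw size")
})

test_that("reward-site/return-trip splits clip ITIs at the zone boundary", {
  s <- generate_session(quick_cfg(n_neurons = 4, n_trials = 6,
                                  return_time_s = 6))
  rs <- suppressWarnings(split_iti_activity(s, "reward_site"))
  rt <- suppressWarnings(split_iti_activity(s, "return_trip"))
  # dwell time at the reward site is the ITI minus the return run, up to
  # the frames spent covering the first 10 cm of the goal arm
  for (row in seq_len(nrow(rs$itis))) {
    t <- rs$itis$iti[row]
    expected_dwell <- s$itis$duration_s[t] - 6
    expect_lt(abs(rs$itis$duration_s[row] - expected_dwell), 1.2)
  }
  # clipped intervals stay inside their source ITI and do not overlap
  for (row in seq_len(nrow(rt$itis))) {
    t <- rt$itis$iti[row]
    expect_gte(rt$itis$t_start_s[row], s$itis$t_start_s[t])
    expect_lte(rt$itis$t_end_s[row], s$itis$t_end_s[t] + 1e-9)
  }
  # stationary animal never leaves the reward zone: return trip empty
  st <- generate_session(quick_cfg(n_neurons = 4, n_trials = 4,
                                   stationary = TRUE))
  expect_error(suppressWarnings(split_iti_activity(st, "return_trip")),
               "no ITI")
  # zero radius: no sample within the reward zone
  expect_error(suppressWarnings(
    split_iti_activity(s, "reward_site", radius_cm = 0)), "no ITI")
})

test_that("recall outputs keep symmetry and range on random sessions", {
  for (seed in 1:3) {
    s <- generate_session(quick_cfg(n_neurons = 8, n_trials = 8,
                                    coupling = ifelse(seed == 2, 1, 0),
                                    seed = seed))
    R <- recall_matrix(s, sigma = 0.1, dt = 0.02)
    E <- expected_recall_matrix(s, sigma = 0.1, dt = 0.02,
                                n_shuffles = 3, seed = seed)
    res <- residual_recall(R, E)
    for (M in list(R, E)) {
      expect_true(isSymmetric(unclass(M)))
      expect_true(all(M >= 0 & M <= 1))
    }
    expect_true(all(res >= -1 & res <= 1))
  }
})
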