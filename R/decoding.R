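#' Position-binned firing-rate vectors for every ITI
#'
#' For each ITI and each of the five linearised maze sections, the firing
#' rate of every core neuron: spike count inside the section's occupancy
#' frames during that ITI, divided by the total occupancy time. Occupancy
#' may be fragmented (re-entries are summed). Sections an ITI never visits
#' get NA rates and zero occupancy and are excluded from decoding.
#'
#' @param session a \code{maze_session}.
#' @param core core-population indices; computed if NULL.
#' @param sections per-sample section table from [linearise()]; computed
#'   if NULL.
#' @return list of class \code{rate_vectors}: \code{rates} (array
#'   T x 5 x N, Hz), \code{occupancy} (T x 5, seconds), \code{core}.
#' @export
rate_vectors <- function(session, core = NULL, sections = NULL) {
  if (is.null(core)) core <- core_population(session)
  if (is.null(sections)) sections <- linearise(session)
  T_ <- nrow(session$itis)
  N <- length(core)
  frame <- median(diff(session$tracking$time_s))
  rates <- array(NA_real_, c(T_, 5, N))
  occ <- matrix(0, T_, 5)
  for (t in seq_len(T_)) {
    st <- sections[sections$iti == t & !is.na(sections$section), ]
    if (!nrow(st)) next
    # dwell of each sample: gap to next sample, last one gets a frame
    dwell <- c(diff(st$time_s), frame)
    dwell[dwell > 2 * frame] <- frame  # tracking gaps don't inflate dwell
    for (p in 1:5) {
      sel <- st$section == p
      if (!any(sel)) next
      occ[t, p] <- sum(dwell[sel])
      # assign spikes to samples: frame of sample i is [time_i, time_i+dwell_i)
      t0 <- st$time_s[sel]; t1 <- t0 + dwell[sel]
      for (j in seq_len(N)) {
        sp <- session$spikes[[core[j]]]
        cnt <- sum(vapply(seq_along(t0), function(i)
          sum(sp >= t0[i] & sp < t1[i]), numeric(1)))
        rates[t, p, j] <- cnt / occ[t, p]
      }
    }
  }
  structure(list(rates = rates, occupancy = occ, core = core),
            class = "rate_vectors")
}

# ---- decoders --------------------------------------------------------------

# ridge-penalised logistic regression fit by IRLS; lambda on slopes only.
# A mild penalty keeps weights finite on linearly separable data without
# measurably moving the decision boundary.
ridge_logistic_fit <- function(X, y01, lambda = 1e-2, maxit = 50,
                               tol = 1e-8) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y01 - mu) / w
    H <- crossprod(X1 * w, X1) + pen
    new_beta <- solve(H, crossprod(X1 * w, z))
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  drop(beta)
}

predict_one <- function(decoder, Xtr, ytr, xte) {
  lv <- levels(ytr)
  switch(decoder,
    logistic = {
      b <- ridge_logistic_fit(Xtr, as.integer(ytr == lv[2]))
      if (drop(c(1, xte) %*% b) > 0) lv[2] else lv[1]
    },
    lda = {
      fit <- suppressWarnings(MASS::lda(Xtr, grouping = ytr))
      as.character(predict(fit, matrix(xte, 1))$class)
    },
    svm_linear = {
      fit <- e1071::svm(Xtr, ytr, type = "C-classification",
                        kernel = "linear", cost = 1, scale = FALSE)
      as.character(predict(fit, matrix(xte, 1)))
    },
    nearest_neighbour = {
      d <- sqrt(colSums((t(Xtr) - xte)^2))
      nearest <- which(d == min(d))
      labs <- ytr[nearest]
      # deterministic tie-break: the lower class index wins
      lv[min(as.integer(labs))]
    },
    stop("unknown decoder: ", decoder))
}

#' Leave-one-out cross-validated decoding accuracy
#'
#' Each ITI is held out in turn; the decoder is trained on the remaining
#' rate vectors and predicts the held-out label. Accuracy is the fraction
#' of correct predictions. All four decoders are linear and deterministic
#' (nearest-neighbour distance ties break to the lower class index).
#'
#' @param X numeric matrix, examples x neurons.
#' @param y two-level factor of labels.
#' @param decoder "logistic" (ridge-penalised, threshold 0.5), "lda",
#'   "svm_linear" or "nearest_neighbour".
#' @return LOOCV accuracy in [0, 1].
#' @export
decode_feature <- function(X, y, decoder = "logistic") {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("labels are single-class; decoding impossible")
  if (any(table(y) < 2)) stop("need >= 2 examples per label")
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    yt <- droplevels(y[-i])
    if (nlevels(yt) < 2) { pred[i] <- NA_character_; next }
    pred[i] <- predict_one(decoder, X[-i, , drop = FALSE], yt, X[i, ])
  }
  mean(pred == as.character(y), na.rm = FALSE)
}

#' Shuffled-label chance distribution for a decoder
#'
#' Repeats the identical LOOCV procedure after permuting the labels across
#' ITIs, giving the decoding accuracy expected from label frequencies and
#' the decoder alone. Relative accuracy is the true accuracy minus the
#' mean of this distribution.
#'
#' @inheritParams decode_feature
#' @param n_shuffles number of label permutations (default 50).
#' @param seed optional integer seed.
#' @return list: \code{accuracy} (true), \code{chance} (vector of
#'   shuffled accuracies), \code{chance_mean}, \code{relative}.
#' @export
chance_distribution <- function(X, y, decoder = "logistic",
                                n_shuffles = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- decode_feature(X, y, decoder)
  ch <- vapply(seq_len(n_shuffles), function(s)
    decode_feature(X, sample(y), decoder), numeric(1))
  list(accuracy = acc, chance = ch, chance_mean = mean(ch),
       relative = acc - mean(ch))
}

#' Position-dependent decoding of a task feature across a session
#'
#' Runs [decode_feature()] and [chance_distribution()] at each of the five
#' maze sections, using the ITIs with non-zero occupancy of that section
#' and a defined label (identical design for true and shuffled fits).
#'
#' @param session a \code{maze_session}.
#' @param feature grouping name accepted by [label_itis()] (except
#'   path_length): "prior_outcome", "prior_arm", "prior_cue",
#'   "next_outcome", "next_arm", "next_cue".
#' @param decoder as in [decode_feature()].
#' @param rv precomputed [rate_vectors()]; computed if NULL.
#' @param n_shuffles,seed passed to [chance_distribution()].
#' @return data frame of class \code{decoding_result}: one row per
#'   section with \code{accuracy}, \code{chance_mean}, \code{relative},
#'   \code{n_examples} (NA rows where a section lacks two examples of
#'   either label).
#' @export
decode_session <- function(session, feature, decoder = "logistic",
                           rv = NULL, n_shuffles = 50, seed = NULL) {
  if (is.null(rv)) rv <- rate_vectors(session)
  labels <- label_itis(session, feature)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(1:5, function(p) {
    keep <- which(rv$occupancy[, p] > 0 & !is.na(labels))
    out <- data.frame(section = p, feature = feature, decoder = decoder,
                      accuracy = NA_real_, chance_mean = NA_real_,
                      relative = NA_real_, n_examples = length(keep))
    if (length(keep) < 4) return(out)
    y <- droplevels(labels[keep])
    if (nlevels(y) < 2 || any(table(y) < 2)) return(out)
    X <- rv$rates[keep, p, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = dim(rv$rates)[3])
    cd <- chance_distribution(X, y, decoder, n_shuffles)
    out$accuracy <- cd$accuracy
    out$chance_mean <- cd$chance_mean
    out$relative <- cd$relative
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("decoding_result", "data.frame")
  res
}

#' Single-neuron tuning to a task feature at one maze position
#'
#' Splits each neuron's per-ITI firing rates at a section into the two
#' label groups and applies a two-sample Kolmogorov-Smirnov test; a neuron
#' is tuned when p < alpha. Neurons with a degenerate group (fewer than
#' two rates) are skipped with a warning.
#'
#' @param rates numeric matrix, ITIs x neurons, at one section.
#' @param labels two-level factor, one per ITI.
#' @param alpha significance level (default 0.05).
#' @return data frame: \code{neuron}, \code{ks_stat}, \code{p}, \code{tuned}.
#' @export
single_neuron_tuning <- function(rates, labels, alpha = 0.05) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2)
  out <- lapply(seq_len(ncol(rates)), function(j) {
    a <- rates[labels == levels(labels)[1], j]
    b <- rates[labels == levels(labels)[2], j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      warning("neuron ", j, " skipped: degenerate group")
      return(data.frame(neuron = j, ks_stat = NA_real_, p = NA_real_,
                        tuned = NA))
    }
    ks <- suppressWarnings(ks.test(a, b, exact = FALSE))
    data.frame(neuron = j, ks_stat = unname(ks$statistic), p = ks$p.value,
               tuned = ks$p.value < alpha)
  })
  do.call(rbind, out)
}
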