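#' Configuration for a full analysis run
#'
#' Bundles the tunable parameters of every stage. Defaults follow the
#' analysis conventions used throughout the package: 100 ms Gaussian
#' width (the similarity timescale), 10 ms density grid, 1000 ISI
#' shuffles for the expected recall matrix, 50 label shuffles per decoder,
#' 10000 permutations for the cohort test, alpha 0.05.
#'
#' @param sigma Gaussian width, seconds; must lie in the supported sweep
#'   range [0.02, 0.24].
#' @param dt density grid step; default \code{min(0.01, sigma/5)}.
#' @param n_shuffles_recall shuffles for [expected_recall_matrix()].
#' @param n_shuffles_decoder label shuffles for [chance_distribution()].
#' @param n_perm permutations for [session_permutation_test()].
#' @param alpha significance level for KS-based decisions.
#' @param seed master seed; each stage derives its own stream.
#' @param groupings block-comparison groupings to run.
#' @param features decoding features to run.
#' @param decoders decoders to run.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(sigma = 0.1, dt = NULL, n_shuffles_recall = 1000,
                       n_shuffles_decoder = 50, n_perm = 10000,
                       alpha = 0.05, seed = 1L,
                       groupings = c("prior_outcome", "prior_arm",
                                     "prior_cue", "next_outcome"),
                       features = c("prior_outcome", "prior_arm",
                                    "prior_cue", "next_outcome"),
                       decoders = "logistic") {
  if (sigma < 0.02 || sigma > 0.24)
    stop("sigma must lie in [0.02, 0.24] s")
  if (is.null(dt)) dt <- min(0.01, sigma / 5)
  if (dt <= 0 || n_shuffles_recall < 1 || n_shuffles_decoder < 1 ||
      n_perm < 1 || alpha <= 0 || alpha >= 1)
    stop("invalid run configuration")
  structure(list(sigma = sigma, dt = dt,
                 n_shuffles_recall = n_shuffles_recall,
                 n_shuffles_decoder = n_shuffles_decoder, n_perm = n_perm,
                 alpha = alpha, seed = as.integer(seed),
                 groupings = groupings, features = features,
                 decoders = decoders), class = "run_config")
}

#' Run the full analysis on one session
#'
#' Executes, in order: behavioural classification; raw, expected and
#' residual recall matrices; block comparisons for every configured
#' grouping; onset/offset change-point detection; trial-vs-ITI similarity;
#' and position-dependent decoding for every configured feature and
#' decoder. A stage that fails is recorded in \code{$errors} and its
#' dependants are skipped. The report carries a manifest (config and seed)
#' sufficient to reproduce it exactly.
#'
#' @param session a \code{maze_session}.
#' @param config a [run_config()].
#' @param out_dir optional directory: writes \code{report.json} plus the
#'   three recall matrices as CSV.
#' @return list of class \code{session_report}.
#' @export
run_session <- function(session, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  rep <- list(manifest = list(config = unclass(config),
                              n_neurons = length(session$spikes),
                              n_trials = nrow(session$trials)),
              errors = list())
  note <- function(stage, e) rep$errors[[stage]] <<- conditionMessage(e)

  rep$behaviour <- tryCatch(unclass(classify_session(session$trials)),
                            error = function(e) { note("behaviour", e); NULL })
  recall <- tryCatch({
    core <- core_population(session)
    raw <- recall_matrix(session, config$sigma, config$dt, core)
    exp_ <- expected_recall_matrix(session, config$sigma, config$dt, core,
                                   n_shuffles = config$n_shuffles_recall,
                                   seed = derive_seed(config$seed, "spikes"))
    list(core = core, raw = raw, expected = exp_,
         residual = residual_recall(raw, exp_))
  }, error = function(e) { note("recall", e); NULL })

  if (!is.null(recall)) {
    rep$recall <- list(core_size = length(recall$core))
    rep$blocks <- lapply(setNames(config$groupings, config$groupings),
      function(g) tryCatch({
        unclass(block_compare(recall$residual, label_itis(session, g)))
      }, error = function(e) { note(paste0("block_", g), e); NULL }))
    rep$changepoint <- tryCatch(
      unclass(detect_onset_offset(recall$residual,
                                  alpha = config$alpha))[
        c("onset_trial", "offset_trial", "onset_stat", "offset_stat",
          "onset_p", "offset_p")],
      error = function(e) { note("changepoint", e); NULL })
  }

  rep$trial_iti <- tryCatch({
    r <- trial_iti_similarity(session, config$sigma, config$dt,
                              n_shuffles = config$n_shuffles_decoder,
                              seed = derive_seed(config$seed, "tracking"))
    list(p_sign = r$p_sign, mean_delta_within = mean(r$delta_within),
         n_pairs = r$n_pairs)
  }, error = function(e) { note("trial_iti", e); NULL })

  rep$decoding <- tryCatch({
    rv <- rate_vectors(session)
    out <- list()
    for (dec in config$decoders)
      for (f in config$features) {
        key <- paste(dec, f, sep = ".")
        out[[key]] <- tryCatch(
          as.data.frame(decode_session(
            session, f, dec, rv = rv,
            n_shuffles = config$n_shuffles_decoder,
            seed = derive_seed(config$seed, "behaviour"))),
          error = function(e) { note(paste0("decode_", key), e); NULL })
      }
    out
  }, error = function(e) { note("decoding", e); NULL })

  class(rep) <- "session_report"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(recall)) {
      write.csv(unclass(recall$raw),
                file.path(out_dir, "recall_raw.csv"), row.names = FALSE)
      write.csv(unclass(recall$expected),
                file.path(out_dir, "recall_expected.csv"), row.names = FALSE)
      write.csv(unclass(recall$residual),
                file.path(out_dir, "recall_residual.csv"), row.names = FALSE)
    }
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  rep
}

#' Run a cohort of sessions and test for systematic recall
#'
#' Applies [run_session()] to every session, collects the per-session
#' recall differences for each grouping, and runs the cross-session
#' permutation test on the learning-labelled subset (does the full set of
#' learning sessions show positive residual recall difference more often
#' than random subsets would?).
#'
#' @param sessions list of \code{maze_session} objects.
#' @param config a [run_config()].
#' @param out_dir optional directory: per-session subdirectories plus
#'   \code{cohort.json}.
#' @return list of class \code{cohort_report}: \code{sessions} (reports),
#'   \code{deltas} (matrix session x grouping), \code{labels}
#'   (behavioural labels), \code{perm_p} (per grouping; NA when no
#'   learning session exists).
#' @export
run_cohort <- function(sessions, config = run_config(), out_dir = NULL) {
  if (length(sessions) == 0) stop("empty cohort")
  reports <- lapply(seq_along(sessions), function(i)
    run_session(sessions[[i]], config,
                out_dir = if (is.null(out_dir)) NULL
                          else file.path(out_dir, sprintf("session%02d", i))))
  labels <- vapply(reports, function(r)
    r$behaviour$label %||% NA_character_, character(1))
  deltas <- vapply(config$groupings, function(g)
    vapply(reports, function(r) r$blocks[[g]]$delta %||% NA_real_,
           numeric(1)), numeric(length(reports)))
  deltas <- matrix(deltas, nrow = length(reports),
                   dimnames = list(NULL, config$groupings))
  learn <- which(labels == "learning")
  perm_p <- vapply(config$groupings, function(g) {
    d <- deltas[, g]
    if (length(learn) == 0 || anyNA(d)) return(NA_real_)
    session_permutation_test(d, learn, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "rates"))
  }, numeric(1))
  out <- structure(list(sessions = reports, deltas = deltas,
                        labels = labels, learning_ids = learn,
                        perm_p = perm_p), class = "cohort_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(labels = labels, deltas = as.data.frame(deltas),
                              perm_p = as.list(perm_p)),
                         file.path(out_dir, "cohort.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
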