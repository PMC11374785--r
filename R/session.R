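#' Simulate a full game session for one player
#'
#' Generates the 40 training trials followed by the 456 test trials with the
#' printed composition: 126 regular, 126 mismatching-flanker, 84 lava trials
#' (42 matching / 42 mismatching flankers, never on ice), and 120 ice trials
#' with flanker conditions spread equally (60/60). Training trials are
#' regular/mismatching trials and warm up the response-window staircase.
#' Trial order is a uniformly random interleaving subject to the composition.
#' The response window adapts on non-ice, non-lava outcomes; the two
#' stop-signal-delay staircases adapt independently on their lava trials.
#'
#' The result is deterministic given `(profile, config, seed)`.
#'
#' @param profile One-row player profile from [sample_player_profiles()].
#' @param config A [game_config()].
#' @param seed Optional integer seed.
#' @param lava_correction_prob Probability a released response is followed
#'   by a corrective response.
#' @return A data.frame with one row per trial: `player_id`, `trial_index`,
#'   `phase` (training/test), `flanker_mismatch`, `ice`, `lava`, `ssd`,
#'   `go_window`, `responded`, `first_response_time`,
#'   `first_response_correct`, `reversal_time`, `release_time`,
#'   `correction_after_release_time`, `success`. Event times are in ms from
#'   the central colour assignment; absent events are `NA`.
#' @export
#' @examples
#' prof <- sample_player_profiles(population_params(), 1, seed = 1)
#' trials <- simulate_session(prof, game_config(), seed = 7)
#' table(trials$phase)
simulate_session <- function(profile, config = game_config(), seed = NULL,
                             lava_correction_prob = 0.7) {
  validate_game_config(config)
  validate_profile(profile)
  with_seed(seed, {
    plan <- session_plan(config)
    n <- nrow(plan)
    steps <- go_window_steps(config)
    win <- staircase_state("go_window", config$initial_go_window,
                           step_up = steps$up, step_down = steps$down)
    ssd_sc <- list(
      match = staircase_state("ssd_match", config$initial_ssd,
                              config$ssd_step, config$ssd_step),
      mismatch = staircase_state("ssd_mismatch", config$initial_ssd,
                                 config$ssd_step, config$ssd_step)
    )
    ssd <- rep(NA_real_, n); go_window <- numeric(n)
    responded <- logical(n); success <- logical(n)
    frt <- rep(NA_real_, n); fcorr <- rep(NA, n)
    rev_t <- rep(NA_real_, n); rel_t <- rep(NA_real_, n); corr_t <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      go_window[i] <- win$current_value
      if (plan$lava[i]) {
        key <- if (plan$flanker_mismatch[i]) "mismatch" else "match"
        ssd[i] <- ssd_sc[[key]]$current_value
        tr <- stop_trial_core(profile, plan$flanker_mismatch[i], ssd[i],
                              win$current_value, lava_correction_prob)
        responded[i] <- tr$responded; success[i] <- tr$success
        frt[i] <- tr$first_response_time; fcorr[i] <- tr$first_response_correct
        rel_t[i] <- tr$release_time
        corr_t[i] <- tr$correction_after_release_time
        ssd_sc[[key]] <- staircase_update(ssd_sc[[key]], tr$responded)
      } else {
        tr <- choice_trial_core(profile, plan$flanker_mismatch[i], plan$ice[i],
                                win$current_value)
        responded[i] <- tr$responded; success[i] <- tr$success
        frt[i] <- tr$first_response_time; fcorr[i] <- tr$first_response_correct
        rev_t[i] <- tr$reversal_time
        if (!plan$ice[i]) win <- staircase_update(win, tr$success)
      }
    }
    data.frame(
      player_id = if ("player_id" %in% names(profile)) profile$player_id else 1L,
      trial_index = seq_len(n), phase = plan$phase,
      flanker_mismatch = plan$flanker_mismatch, ice = plan$ice, lava = plan$lava,
      ssd = ssd, go_window = go_window, responded = responded,
      first_response_time = frt, first_response_correct = fcorr,
      reversal_time = rev_t, release_time = rel_t,
      correction_after_release_time = corr_t, success = success
    )
  })
}

# Random trial ordering with the configured composition. Training trials are
# split as evenly as possible between matching and mismatching flankers.
session_plan <- function(config) {
  n_tr <- config$n_training
  tr_mis <- n_tr %/% 2L
  training <- data.frame(
    phase = "training",
    flanker_mismatch = sample(rep(c(FALSE, TRUE), c(n_tr - tr_mis, tr_mis))),
    ice = FALSE, lava = FALSE
  )
  n_ice_mis <- config$n_ice %/% 2L
  test <- data.frame(
    phase = "test",
    flanker_mismatch = c(rep(FALSE, config$n_regular), rep(TRUE, config$n_mismatch),
                         rep(FALSE, config$n_ice - n_ice_mis), rep(TRUE, n_ice_mis),
                         rep(FALSE, config$lava_match_split[1L]),
                         rep(TRUE, config$lava_match_split[2L])),
    ice = c(rep(FALSE, config$n_regular + config$n_mismatch),
            rep(TRUE, config$n_ice), rep(FALSE, config$n_lava)),
    lava = c(rep(FALSE, config$n_regular + config$n_mismatch + config$n_ice),
             rep(TRUE, config$n_lava))
  )
  test <- test[sample.int(nrow(test)), , drop = FALSE]
  plan <- rbind(training, test)
  rownames(plan) <- NULL
  plan
}

#' Simulate a cohort of players
#'
#' Draws `n_players` profiles from `pop` and simulates one session per
#' player, returning the pooled trial log together with the ground-truth
#' profile table needed for parameter-recovery studies.
#'
#' @param pop A [population_params()].
#' @param n_players Number of players (>= 1).
#' @param config A [game_config()].
#' @param seed Optional integer seed; fixing it makes the whole cohort
#'   (trials and truth table) reproducible.
#' @return A list of class `"com_cohort"`: `trials` (row-bound session
#'   logs), `truth` (profile table keyed by `player_id`), `config`, `pop`.
#' @export
simulate_cohort <- function(pop, n_players, config = game_config(), seed = NULL) {
  n_players <- as.integer(n_players)
  if (n_players < 1L) stop("n_players must be >= 1")
  truth <- sample_player_profiles(pop, n_players, seed = child_seed(seed, 0L))
  sessions <- lapply(seq_len(n_players), function(i) {
    simulate_session(truth[i, , drop = FALSE], config,
                     seed = child_seed(seed, i),
                     lava_correction_prob = pop$lava_correction_prob)
  })
  trials <- do.call(rbind, sessions)
  rownames(trials) <- NULL
  structure(list(trials = trials, truth = truth, config = config, pop = pop),
            class = "com_cohort")
}

#' @export
print.com_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$truth), "players,",
      nrow(x$trials), "trials\n")
  invisible(x)
}

#' Write or read session logs and truth tables as CSV
#'
#' One row per trial with the trial-record field names as header; absent
#' events are written as empty cells. Times are in ms.
#'
#' @param trials,truth Data frames as returned in [simulate_cohort()].
#' @param path Output file.
#' @return The path, invisibly; readers return the data.frame.
#' @export
write_session_log <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  df <- read.csv(path, na.strings = "")
  for (nm in c("flanker_mismatch", "ice", "lava", "responded",
               "first_response_correct", "success"))
    if (nm %in% names(df)) df[[nm]] <- as.logical(df[[nm]])
  df
}

#' @rdname write_session_log
#' @export
write_truth_table <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE, na = "")
  invisible(path)
}
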