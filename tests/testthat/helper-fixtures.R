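# Shared fixtures. Everything is generated in code; the cohort used by
# several files is built lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

with_seed_test <- function(seed, expr) changeofmind:::with_seed(seed, expr)

# A fully specified player profile with overridable fields; defaults give a
# well-behaved mid-range player.
make_profile <- function(...) {
  prof <- data.frame(
    player_id = 1L, drift_base = 0.055, boundary = 18, start_var = 0.2,
    nondecision = 250, post_gain = 3.2, correction_engage = 1,
    guess_base = 0, guess_flanker = 0, guess_ice = 0,
    flanker_capture = 0, ice_capture = 0, reconsider_lag = 0,
    flanker_misdirection = 0, ice_misdirection = 0,
    flanker_decrement_pre = 0, flanker_decrement_post = 0,
    ice_decrement_pre = 0, ice_modifier_post = 0,
    stop_latency_mean = 250, release_latency_mean = 250, stop_latency_sd = 30,
    stop_flanker_effect = 0, correction_latency_mean = 191,
    lapse = 0, fps = 57
  )
  over <- list(...)
  prof[names(over)] <- over
  prof
}

# Hand-built trial-log rows for the preprocessing and measure tests.
make_trial <- function(player_id = 1L, trial_index = 1L, phase = "test",
                       flanker_mismatch = FALSE, ice = FALSE, lava = FALSE,
                       ssd = NA_real_, go_window = 1317, responded = TRUE,
                       first_response_time = 500,
                       first_response_correct = TRUE,
                       reversal_time = NA_real_, release_time = NA_real_,
                       correction_after_release_time = NA_real_,
                       success = TRUE) {
  data.frame(player_id = player_id, trial_index = trial_index, phase = phase,
             flanker_mismatch = flanker_mismatch, ice = ice, lava = lava,
             ssd = ssd, go_window = go_window, responded = responded,
             first_response_time = first_response_time,
             first_response_correct = first_response_correct,
             reversal_time = reversal_time, release_time = release_time,
             correction_after_release_time = correction_after_release_time,
             success = success)
}

# Default-population cohort shared across test files (30 players).
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(population_params(), 30,
                                           game_config(), seed = 20240901)
  }
  .fixture_env$cohort
}

# Preprocessed view of the shared cohort: exclusions applied, filtered
# measure tables, eligibility flags.
shared_measures <- function() {
  if (is.null(.fixture_env$measures)) {
    coh <- shared_cohort()
    excl <- score_player_exclusions(coh$trials,
                                    coh$truth[, c("player_id", "fps")])
    keep <- excl$player_id[!excl$excluded]
    trials <- coh$trials[coh$trials$player_id %in% keep, ]
    resp <- filter_trials(filter_trials(extract_response_table(trials),
                                        "rt1")$table, "correction")$table
    tts <- filter_trials(extract_tts_table(trials), "correction")$table
    elig <- measure_eligibility(resp, tts, trials)
    .fixture_env$measures <- list(trials = trials, responses = resp,
                                  tts = tts, eligibility = elig,
                                  exclusions = excl)
  }
  .fixture_env$measures
}

# Cohort-level pipeline steps used by the heavier model tests.
fit_joint_from_cohort <- function(cohort, conflict = "flanker") {
  excl <- score_player_exclusions(cohort$trials,
                                  cohort$truth[, c("player_id", "fps")])
  trials <- cohort$trials[cohort$trials$player_id %in%
                            excl$player_id[!excl$excluded], ]
  resp <- filter_trials(filter_trials(extract_response_table(trials),
                                      "rt1")$table, "correction")$table
  tts <- filter_trials(extract_tts_table(trials), "correction")$table
  elig <- measure_eligibility(resp, tts, trials)
  ids <- elig$player_id[elig[[conflict]]]
  tab <- changeofmind:::conflict_model_data(
    resp[resp$player_id %in% ids, ], conflict)
  suppressMessages(conflict_model(tab, "maximal_joint"))
}
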