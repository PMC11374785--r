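#' Game session configuration
#'
#' Constants describing one assessment session of the tunnel-running game:
#' trial composition, stimulus timing, and the two adaptive mechanisms
#' (the success-dependent obstacle-timing window and the +/-50 ms
#' stop-signal-delay staircases).
#'
#' The printed design uses 40 training trials followed by 456 test trials:
#' 126 regular (matching-flanker) trials, 126 mismatching-flanker trials,
#' 84 lava (stop-signal) trials split 42/42 across flanker conditions, and
#' 120 ice (rule-reversal) trials spread equally across flanker conditions.
#' Lava and ice never co-occur. Timing constants: the central rat is coloured
#' 433 ms after obstacle presentation (flankers at 350 ms), the initial
#' response window is 1317 ms, the initial stop-signal delay 300 ms.
#'
#' The response window adapts asymmetrically so that its stationary success
#' rate is `go_success_target` (0.80): a success shortens the window by
#' `go_step_down` ms, a failure lengthens it by
#' `go_step_down * p / (1 - p)` ms. The stop-signal delay staircases move in
#' fixed 50 ms steps, targeting a 50% respond rate.
#'
#' @param n_training,n_regular,n_mismatch,n_lava,n_ice Trial counts.
#' @param lava_match_split Length-2 count vector: lava trials with matching /
#'   mismatching flankers; must sum to `n_lava`.
#' @param central_color_delay,flanker_color_delay Colour-assignment delays
#'   (ms) relative to obstacle presentation. Event times in trial records are
#'   clocked from the central colour assignment.
#' @param initial_go_window Initial response window (ms).
#' @param initial_ssd Initial stop-signal delay (ms).
#' @param ssd_step Stop-signal-delay staircase step (ms).
#' @param go_step_down Window decrement after a success (ms); the increment
#'   after a failure is derived from `go_success_target`.
#' @param go_success_target Stationary success proportion of the window
#'   staircase, in (0,1).
#' @param stop_target Respond-rate targeted by the SSD staircase, in (0,1).
#' @param seed Optional integer default seed carried with the config.
#' @return A list of class `"game_config"`.
#' @seealso [simulate_session()], [staircase_update()]
#' @export
#' @examples
#' cfg <- game_config()
#' cfg$n_regular
game_config <- function(n_training = 40L, n_regular = 126L, n_mismatch = 126L,
                        n_lava = 84L, n_ice = 120L,
                        lava_match_split = c(42L, 42L),
                        central_color_delay = 433, flanker_color_delay = 350,
                        initial_go_window = 1317, initial_ssd = 300,
                        ssd_step = 50, go_step_down = 20,
                        go_success_target = 0.80, stop_target = 0.50,
                        seed = NULL) {
  cfg <- list(
    n_training = as.integer(n_training), n_regular = as.integer(n_regular),
    n_mismatch = as.integer(n_mismatch), n_lava = as.integer(n_lava),
    n_ice = as.integer(n_ice), lava_match_split = as.integer(lava_match_split),
    central_color_delay = central_color_delay,
    flanker_color_delay = flanker_color_delay,
    initial_go_window = initial_go_window, initial_ssd = initial_ssd,
    ssd_step = ssd_step, go_step_down = go_step_down,
    go_success_target = go_success_target, stop_target = stop_target,
    seed = seed
  )
  class(cfg) <- "game_config"
  validate_game_config(cfg)
  cfg
}

validate_game_config <- function(cfg) {
  counts <- c(cfg$n_training, cfg$n_regular, cfg$n_mismatch, cfg$n_lava, cfg$n_ice)
  if (any(counts < 0L)) stop("trial counts must be >= 0")
  if (length(cfg$lava_match_split) != 2L || any(cfg$lava_match_split < 0L))
    stop("lava_match_split must be two non-negative counts")
  if (sum(cfg$lava_match_split) != cfg$n_lava)
    stop("lava_match_split must sum to n_lava")
  if (cfg$ssd_step <= 0 || cfg$go_step_down <= 0) stop("staircase steps must be > 0")
  for (p in c(cfg$go_success_target, cfg$stop_target))
    if (!is.finite(p) || p <= 0 || p >= 1) stop("adaptation targets must lie in (0,1)")
  if (cfg$initial_go_window <= 0) stop("initial_go_window must be > 0")
  if (cfg$initial_ssd < 0) stop("initial_ssd must be >= 0")
  invisible(cfg)
}

#' Population-level generative parameters
#'
#' Means and standard deviations of the per-player generative parameters
#' drawn by [sample_player_profiles()], plus the cross-response-type
#' continuity correlations. A player's initial response arises from a
#' drift-diffusion process (drift `drift_base`, symmetric boundaries
#' `+/-boundary`, non-decision time `nondecision`, unit diffusion
#' coefficient, ms time unit); after an incorrect first crossing the same
#' accumulator continues toward the correct boundary with drift
#' `post_gain * drift_base` minus the post-decision conflict decrements.
#' Response inhibition follows an independent race: a stop process finishing
#' at `ssd + stop latency` competes with the go process.
#'
#' Conflict acts in two ways: a pre-decision *misdirection phase*
#' (`flanker_misdirection` / `ice_misdirection`, ms) during which the drift
#' points toward the conflict-implied incorrect response (this carries the
#' individual differences in conflict effects on first responses), and drift
#' decrements (`*_decrement_pre`, and `*_decrement_post` /
#' `ice_modifier_post` acting on the post-decision continuation).
#'
#' Continuity knobs:
#' * `continuity_flanker` -- correlation between a player's pre-decision
#'   flanker interference (misdirection duration) and the post-decision
#'   flanker drift decrement. At 1 the interference acting on
#'   error-correcting responses is the same latent quantity that acts on
#'   initial responses.
#' * `continuity_ice` -- the analogous correlation for the ice
#'   (rule-reversal) effect. The default is negative: the discontinuous
#'   regime, in which players with strong initial ice interference have
#'   relatively facilitated post-decision corrections.
#' * `stop_share` -- correlation between the latent stop latency expressed in
#'   the inhibition race (SSRT) and in the release of an ongoing response
#'   (time-to-stop).
#'
#' Remaining fields are `<name>_mean` / `<name>_sd` pairs; see
#' [sample_player_profiles()] for the profile fields themselves. `lapse`
#' is a per-trial probability of not responding at all on a non-lava trial,
#' included so that non-response exclusion rules are exercised; `fps` is a
#' per-player constant frame rate used only by the exclusion rules.
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `"population_params"`.
#' @export
#' @examples
#' pop <- population_params(continuity_flanker = 1)
#' pop$continuity_flanker
population_params <- function(...) {
  pop <- list(
    drift_base_mean = 0.055, drift_base_sd = 0.009,
    boundary_mean = 18, boundary_sd = 2.2,
    start_var_mean = 0.20, start_var_sd = 0.05,
    nondecision_mean = 250, nondecision_sd = 25,
    post_gain_mean = 3.2, post_gain_sd = 0.35,
    correction_engage_mean = 0.50, correction_engage_sd = 0.15,
    guess_base_mean = 0.35, guess_base_sd = 0.08,
    guess_flanker_mean = 0.00, guess_flanker_sd = 0.00,
    guess_ice_mean = 0.00, guess_ice_sd = 0.00,
    flanker_capture_mean = 0.16, flanker_capture_sd = 0.05,
    ice_capture_mean = 0.22, ice_capture_sd = 0.06,
    flanker_misdirection_mean = 70, flanker_misdirection_sd = 38,
    ice_misdirection_mean = 85, ice_misdirection_sd = 32,
    flanker_decrement_pre_mean = 0.002, flanker_decrement_pre_sd = 0.001,
    flanker_decrement_post_mean = 0.025, flanker_decrement_post_sd = 0.065,
    ice_decrement_pre_mean = 0.002, ice_decrement_pre_sd = 0.001,
    ice_modifier_post_mean = 0.012, ice_modifier_post_sd = 0.045,
    stop_latency_mean_mean = 250, stop_latency_mean_sd = 40,
    stop_latency_sd_mean = 30, stop_latency_sd_sd = 8,
    stop_flanker_effect_mean = 15, stop_flanker_effect_sd = 8,
    reconsider_lag_mean = 150, reconsider_lag_sd = 40,
    correction_latency_mean_mean = 191, correction_latency_mean_sd = 25,
    correction_latency_within_sd = 40,
    lava_correction_prob = 0.70,
    lapse_mean = 0.015, lapse_sd = 0.008,
    fps_mean = 57, fps_sd = 4,
    continuity_flanker = 0.8,
    continuity_ice = -0.9,
    stop_share = 0.9
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(pop))
    if (length(bad)) stop("unknown population parameter(s): ", paste(bad, collapse = ", "))
    pop[names(over)] <- over
  }
  class(pop) <- "population_params"
  validate_population_params(pop)
  pop
}

validate_population_params <- function(pop) {
  sds <- unlist(pop[grepl("_sd$", names(pop))])
  if (any(!is.finite(sds)) || any(sds < 0)) stop("population SDs must be finite and >= 0")
  for (nm in c("continuity_flanker", "continuity_ice", "stop_share")) {
    r <- pop[[nm]]
    if (!is.finite(r) || r < -1 || r > 1)
      stop(nm, " must be a correlation in [-1, 1]; the implied per-pair ",
           "correlation matrix is not positive semi-definite otherwise")
  }
  if (pop$lava_correction_prob < 0 || pop$lava_correction_prob > 1)
    stop("lava_correction_prob must lie in [0, 1]")
  invisible(pop)
}

#' Read or write configuration as JSON
#'
#' Serialises a [game_config()] / [population_params()] pair (keys are the
#' field names) so that runs can be reproduced from a config file.
#'
#' @param game A `game_config`.
#' @param pop A `population_params`.
#' @param path File path.
#' @return `read_config_json()` returns `list(game = , pop = )`.
#' @export
write_config_json <- function(game, pop, path) {
  jsonlite::write_json(list(game = unclass(game), pop = unclass(pop)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  game <- do.call(game_config, raw$game[!vapply(raw$game, is.null, TRUE)])
  pop <- do.call(population_params,
                 raw$pop[setdiff(names(raw$pop), character(0))])
  list(game = game, pop = pop)
}
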