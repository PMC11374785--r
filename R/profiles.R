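#' Draw per-player generative profiles from a population
#'
#' Samples `n` player profiles from the population described by a
#' [population_params()] object. Three parameter pairs are drawn from
#' bivariate normal distributions with the configured cross-correlations:
#' the flanker misdirection duration and post-decision flanker decrement
#' (`continuity_flanker`), the ice misdirection duration and post-decision
#' ice modifier (`continuity_ice`), and the latent stop latency expressed
#' in the
#' inhibition race versus in the release of an ongoing response
#' (`stop_share`). All other fields are independent normals. Fields with a
#' hard physical support (boundary, non-decision time, latencies, fps,
#' lapse probability) are truncated to that support.
#'
#' @param pop A [population_params()] object.
#' @param n Number of players (>= 0).
#' @param seed Optional integer seed; a fixed seed makes the draw
#'   reproducible without disturbing the caller's RNG stream.
#' @return A data.frame with one row per player: `player_id`, `drift_base`,
#'   `boundary`, `start_var` (half-width of the uniform starting-point
#'   distribution as a fraction of the boundary), `nondecision`,
#'   `post_gain`, `correction_engage` (probability of engaging
#'   reconsideration after an incorrect first response), `guess_base`,
#'   `guess_flanker`, `guess_ice` (fast-guess probabilities),
#'   `flanker_capture`, `ice_capture` (conflict-capture error
#'   probabilities), `flanker_misdirection`, `ice_misdirection`
#'   (conflict-resolution delays, ms), `flanker_decrement_pre`,
#'   `flanker_decrement_post`, `ice_decrement_pre`, `ice_modifier_post`,
#'   `stop_latency_mean`, `release_latency_mean`, `stop_latency_sd`,
#'   `stop_flanker_effect`, `correction_latency_mean`, `lapse`, `fps`.
#' @export
#' @examples
#' pop <- population_params()
#' profs <- sample_player_profiles(pop, 5, seed = 1)
#' nrow(profs)
sample_player_profiles <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  validate_population_params(pop)
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  empty <- data.frame(
    player_id = integer(0), drift_base = numeric(0), boundary = numeric(0),
    start_var = numeric(0), nondecision = numeric(0), post_gain = numeric(0),
    correction_engage = numeric(0), guess_base = numeric(0),
    guess_flanker = numeric(0), guess_ice = numeric(0),
    flanker_capture = numeric(0), ice_capture = numeric(0),
    reconsider_lag = numeric(0),
    flanker_misdirection = numeric(0), ice_misdirection = numeric(0),
    flanker_decrement_pre = numeric(0), flanker_decrement_post = numeric(0),
    ice_decrement_pre = numeric(0), ice_modifier_post = numeric(0),
    stop_latency_mean = numeric(0), release_latency_mean = numeric(0),
    stop_latency_sd = numeric(0), stop_flanker_effect = numeric(0),
    correction_latency_mean = numeric(0), lapse = numeric(0), fps = numeric(0)
  )
  if (n == 0L) return(empty)

  with_seed(seed, {
    pair <- function(m1, s1, m2, s2, rho) {
      S <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2L)
      if (s1 == 0 && s2 == 0) {
        matrix(rep(c(m1, m2), each = n), ncol = 2L)
      } else {
        matrix(MASS::mvrnorm(n, mu = c(m1, m2), Sigma = S), ncol = 2L)
      }
    }
    fl <- pair(pop$flanker_misdirection_mean, pop$flanker_misdirection_sd,
               pop$flanker_decrement_post_mean, pop$flanker_decrement_post_sd,
               pop$continuity_flanker)
    ic <- pair(pop$ice_misdirection_mean, pop$ice_misdirection_sd,
               pop$ice_modifier_post_mean, pop$ice_modifier_post_sd,
               pop$continuity_ice)
    st <- pair(pop$stop_latency_mean_mean, pop$stop_latency_mean_sd,
               pop$stop_latency_mean_mean, pop$stop_latency_mean_sd,
               pop$stop_share)
    clamp <- function(x, lo, hi = Inf) pmin(pmax(x, lo), hi)
    data.frame(
      player_id = seq_len(n),
      drift_base = clamp(rnorm(n, pop$drift_base_mean, pop$drift_base_sd), 0.005),
      boundary = clamp(rnorm(n, pop$boundary_mean, pop$boundary_sd), 4),
      start_var = clamp(rnorm(n, pop$start_var_mean, pop$start_var_sd), 0, 0.95),
      nondecision = clamp(rnorm(n, pop$nondecision_mean, pop$nondecision_sd), 50),
      post_gain = clamp(rnorm(n, pop$post_gain_mean, pop$post_gain_sd), 1),
      correction_engage = clamp(rnorm(n, pop$correction_engage_mean,
                                      pop$correction_engage_sd), 0.02, 0.98),
      guess_base = clamp(rnorm(n, pop$guess_base_mean, pop$guess_base_sd), 0.01, 0.6),
      guess_flanker = clamp(rnorm(n, pop$guess_flanker_mean, pop$guess_flanker_sd), 0, 0.4),
      guess_ice = clamp(rnorm(n, pop$guess_ice_mean, pop$guess_ice_sd), 0, 0.4),
      flanker_capture = clamp(rnorm(n, pop$flanker_capture_mean, pop$flanker_capture_sd), 0, 0.6),
      ice_capture = clamp(rnorm(n, pop$ice_capture_mean, pop$ice_capture_sd), 0, 0.6),
      reconsider_lag = clamp(rnorm(n, pop$reconsider_lag_mean, pop$reconsider_lag_sd), 0),
      flanker_misdirection = pmax(fl[, 1L], 0),
      ice_misdirection = pmax(ic[, 1L], 0),
      flanker_decrement_pre = clamp(rnorm(n, pop$flanker_decrement_pre_mean,
                                          pop$flanker_decrement_pre_sd), 0),
      flanker_decrement_post = fl[, 2L],
      ice_decrement_pre = clamp(rnorm(n, pop$ice_decrement_pre_mean,
                                      pop$ice_decrement_pre_sd), 0),
      ice_modifier_post = ic[, 2L],
      stop_latency_mean = clamp(st[, 1L], 50),
      release_latency_mean = clamp(st[, 2L], 50),
      stop_latency_sd = clamp(rnorm(n, pop$stop_latency_sd_mean, pop$stop_latency_sd_sd), 1),
      stop_flanker_effect = rnorm(n, pop$stop_flanker_effect_mean, pop$stop_flanker_effect_sd),
      correction_latency_mean =
        clamp(rnorm(n, pop$correction_latency_mean_mean, pop$correction_latency_mean_sd), 60),
      lapse = clamp(rnorm(n, pop$lapse_mean, pop$lapse_sd), 0, 0.2),
      fps = clamp(rnorm(n, pop$fps_mean, pop$fps_sd), 20)
    )
  })
}

validate_profile <- function(profile) {
  need <- c("drift_base", "boundary", "start_var", "nondecision", "post_gain",
            "correction_engage", "guess_base", "guess_flanker", "guess_ice",
            "flanker_capture", "ice_capture", "reconsider_lag",
            "flanker_misdirection", "ice_misdirection",
            "flanker_decrement_pre", "flanker_decrement_post",
            "ice_decrement_pre", "ice_modifier_post",
            "stop_latency_mean", "release_latency_mean", "stop_latency_sd",
            "correction_latency_mean", "lapse")
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop("profile is missing field(s): ", paste(miss, collapse = ", "))
  vals <- unlist(profile[need])
  if (any(!is.finite(vals))) stop("profile contains non-finite parameters")
  if (profile$boundary <= 0) stop("boundary must be > 0")
  if (profile$nondecision < 0) stop("nondecision must be >= 0")
  if (profile$stop_latency_sd < 0) stop("stop_latency_sd must be >= 0")
  invisible(profile)
}
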