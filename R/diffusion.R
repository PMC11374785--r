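# Evidence-accumulation core. Euler-Maruyama with 1 ms steps and unit
# diffusion coefficient; the time unit throughout is milliseconds.

# First passage of a drifting random walk x_{t+1} = x_t + v*dt + sigma*sqrt(dt)*e.
# Returns the crossing step (in steps, NA if no crossing within max_steps) and
# which boundary was hit. Paths are generated in chunks to avoid simulating
# far beyond the crossing.
first_passage <- function(x0, v, lower, upper, max_steps, sigma = 1, dt = 1) {
  if (max_steps < 1L) return(list(step = NA_real_, upper = NA, x_end = x0))
  done <- 0
  x <- x0
  sq <- sigma * sqrt(dt)
  chunk <- 512L
  while (done < max_steps) {
    m <- as.integer(min(chunk, max_steps - done))
    if (m < 1L) break
    path <- x + cumsum(v * dt + sq * rnorm(m))
    hit <- which(path >= upper | path <= lower)
    if (length(hit)) {
      i <- hit[1L]
      return(list(step = done + i, upper = path[i] >= upper, x_end = path[i]))
    }
    done <- done + m
    x <- path[m]
  }
  list(step = NA_real_, upper = NA, x_end = x)
}

# First response: a three-way mixture.
# 1. With probability `p_guess` the response is an impulsive guess (50/50
#    accuracy, fast latency, independent of the conflict condition).
# 2. On conflict trials, with probability `p_capture` the conflict-implied
#    response captures the trial: a fast incorrect response with
#    impulse-like latency (the classic fast-error signature; the conflict
#    was never resolved, so no delay and no conflict-dependent timing).
# 3. Otherwise evidence accumulation starts after the conflict-resolution
#    delay `misdir_steps`; this path carries the conflict slowing of
#    correct first responses.
# Returns the crossing step and boundary, or NA when nothing crosses
# within `max_steps`.
accumulate_first <- function(x0, v_pre, misdir_steps, p_guess, p_capture,
                             a, max_steps, sigma = 1, dt = 1) {
  if (runif(1L) < p_guess) {
    g <- round(max(rnorm(1L, 60, 25), 10) / dt)
    if (g > max_steps) return(list(step = NA_real_, upper = NA))
    return(list(step = g, upper = runif(1L) < 0.5))
  }
  if (runif(1L) < p_capture) {
    g <- round(max(rnorm(1L, 60, 25), 10) / dt)
    if (g > max_steps) return(list(step = NA_real_, upper = NA))
    return(list(step = g, upper = FALSE))
  }
  if (misdir_steps >= max_steps) return(list(step = NA_real_, upper = NA))
  fp <- first_passage(x0, v_pre, -a, a, max_steps - misdir_steps, sigma, dt)
  if (!is.na(fp$step)) fp$step <- fp$step + misdir_steps
  fp
}

# Condition-specific drifts, conflict-resolution delay and guess
# probability for one trial.
trial_drifts <- function(profile, flanker_mismatch, ice) {
  v_pre <- profile$drift_base -
    (if (flanker_mismatch) profile$flanker_decrement_pre else 0) -
    (if (ice) profile$ice_decrement_pre else 0)
  v_post <- profile$post_gain * profile$drift_base -
    (if (flanker_mismatch) profile$flanker_decrement_post else 0) -
    (if (ice) profile$ice_modifier_post else 0)
  misdir <- (if (flanker_mismatch) profile$flanker_misdirection else 0) +
    (if (ice) profile$ice_misdirection else 0)
  p_guess <- profile$guess_base +
    (if (flanker_mismatch) profile$guess_flanker else 0) +
    (if (ice) profile$guess_ice else 0)
  p_capture <- (if (flanker_mismatch) profile$flanker_capture else 0) +
    (if (ice) profile$ice_capture else 0)
  # the post-decision process must keep moving toward the correct boundary
  # (its domain is half-open); the pre-decision process is bounded on both
  # sides, so any drift (including 0) terminates
  list(pre = v_pre, post = max(v_post, 0.02), misdir = misdir,
       p_guess = min(max(p_guess, 0), 0.9),
       p_capture = min(max(p_capture, 0), 0.9))
}

#' Simulate one choice (non-lava) trial
#'
#' A single diffusion accumulator starts at a uniformly drawn point
#' (`start_var` times the boundary wide, emulating premature response
#' preparation) and drifts toward symmetric boundaries at `+/-boundary`;
#' the drift is `drift_base` minus the pre-decision conflict decrements
#' implied by the condition flags. With a condition-dependent probability
#' (`guess_base` plus the conflict increments) the first response is an
#' impulsive fast guess with 50/50 accuracy whose latency does not depend
#' on the conflict; otherwise, on conflict trials, accumulation starts only
#' after a conflict-resolution delay (the player's `flanker_misdirection` /
#' `ice_misdirection` duration, during which the conflict-implied response
#' captures processing). The first
#' boundary crossing plus the non-decision time gives the first response and
#' its correctness (the correct response is the upper boundary by
#' convention). After an incorrect first crossing the *same* accumulator
#' continues from the incorrect boundary with the post-decision drift
#' (`post_gain * drift_base` minus post-decision decrements); reaching the
#' correct boundary initiates the error-correcting response (`reversal_time`,
#' clocked, like all event times, from the central colour assignment). A
#' trial succeeds when the correct boundary is reached within the response
#' window. With probability `lapse` the player does not engage and no
#' response occurs; after an error, reconsideration itself only begins with
#' probability `correction_engage`.
#'
#' @param profile One-row data.frame (or list) of player parameters, see
#'   [sample_player_profiles()].
#' @param flanker_mismatch,ice Condition flags.
#' @param go_window Response window (ms), > 0.
#' @param seed Optional seed making the trial a pure function of its inputs.
#' @param dt Integration step (ms). 1 ms unless the caller needs finer
#'   resolution.
#' @param sigma Diffusion coefficient (evidence / sqrt(ms)).
#' @return One-row data.frame: `responded`, `first_response_time`,
#'   `first_response_correct`, `reversal_time`, `success`.
#' @export
simulate_choice_trial <- function(profile, flanker_mismatch = FALSE, ice = FALSE,
                                  go_window, seed = NULL, dt = 1, sigma = 1) {
  validate_profile(profile)
  if (!is.finite(go_window) || go_window <= 0) stop("go_window must be > 0")
  with_seed(seed, {
    out <- choice_trial_core(profile, flanker_mismatch, ice, go_window, dt, sigma)
    as.data.frame(out)
  })
}

choice_trial_core <- function(profile, flanker_mismatch, ice, go_window,
                              dt = 1, sigma = 1) {
  out <- list(responded = FALSE, first_response_time = NA_real_,
              first_response_correct = NA, reversal_time = NA_real_,
              success = FALSE)
  if (runif(1L) < profile$lapse) return(out)
  a <- profile$boundary
  ter <- profile$nondecision
  v <- trial_drifts(profile, flanker_mismatch, ice)
  max_steps <- floor((go_window - ter) / dt)
  if (max_steps < 1L) return(out)
  # trial-to-trial starting-point variability: premature commitments give
  # fast guesses whose timing is weakly drift-dependent
  x0 <- runif(1L, -profile$start_var * a, profile$start_var * a)
  fp <- accumulate_first(x0, v$pre, round(v$misdir / dt), v$p_guess,
                         v$p_capture, a, max_steps, sigma, dt)
  if (is.na(fp$step)) {
    # deadline pressure: a player who has not decided as the obstacle
    # approaches usually still emits a forced guess just before collision
    if (runif(1L) < 0.85) {
      t_forced <- go_window - max(rnorm(1L, 150, 50), 20)
      if (t_forced > ter) {
        out$responded <- TRUE
        out$first_response_time <- t_forced
        out$first_response_correct <- runif(1L) < 0.5
        out$success <- isTRUE(out$first_response_correct)
      }
    }
    return(out)
  }
  out$responded <- TRUE
  out$first_response_time <- fp$step * dt + ter
  out$first_response_correct <- fp$upper
  if (fp$upper) {
    out$success <- TRUE
    return(out)
  }
  if (runif(1L) >= profile$correction_engage) return(out)  # error never reconsidered
  # reconsideration starts after a post-error processing lag, then the same
  # accumulator races from the incorrect boundary to the correct one
  lag <- round(max(rnorm(1L, profile$reconsider_lag, 50), 0) / dt)
  if (lag >= max_steps - fp$step) return(out)
  rev <- first_passage(-a, v$post, -Inf, a, max_steps - fp$step - lag, sigma, dt)
  if (!is.na(rev$step)) {
    out$reversal_time <- (fp$step + lag + rev$step) * dt + ter
    out$success <- TRUE
  }
  out
}

#' Simulate one lava (stop-signal) trial
#'
#' The go process is the first-crossing machinery of
#' [simulate_choice_trial()]; its finishing time (crossing + non-decision)
#' races an independent stop process finishing at
#' `ssd + N(stop_latency_mean, stop_latency_sd)`. If the stop process wins,
#' no movement occurs and the trial succeeds. Otherwise movement starts at
#' the go time and the ongoing response is released when the player's release
#' process finishes (`ssd +` a latency sharing the trial's stop noise but
#' centred on `release_latency_mean`); with probability
#' `lava_correction_prob` a corrective response follows the release after
#' roughly `correction_latency_mean` ms. On mismatching-flanker lava trials
#' both stop and release latencies are shifted by the player's
#' `stop_flanker_effect`.
#'
#' @inheritParams simulate_choice_trial
#' @param ssd Stop-signal delay (ms, >= 0) from the central colour
#'   assignment.
#' @param lava_correction_prob Probability that a release is followed by a
#'   corrective response (making the trial time-to-stop eligible).
#' @return One-row data.frame: `responded`, `first_response_time`,
#'   `first_response_correct`, `release_time`,
#'   `correction_after_release_time`, `success`.
#' @export
simulate_stop_trial <- function(profile, flanker_mismatch = FALSE, ssd,
                                go_window = 1317, seed = NULL,
                                lava_correction_prob = 0.7, dt = 1, sigma = 1) {
  validate_profile(profile)
  if (!is.finite(ssd) || ssd < 0) stop("ssd must be >= 0")
  with_seed(seed, {
    as.data.frame(stop_trial_core(profile, flanker_mismatch, ssd, go_window,
                                  lava_correction_prob, dt, sigma))
  })
}

stop_trial_core <- function(profile, flanker_mismatch, ssd, go_window,
                            lava_correction_prob, dt = 1, sigma = 1) {
  out <- list(responded = FALSE, first_response_time = NA_real_,
              first_response_correct = NA, release_time = NA_real_,
              correction_after_release_time = NA_real_, success = TRUE)
  a <- profile$boundary
  ter <- profile$nondecision
  v <- trial_drifts(profile, flanker_mismatch, FALSE)
  fe <- if (flanker_mismatch) profile$stop_flanker_effect else 0
  max_steps <- floor((go_window - ter) / dt)
  go <- if (runif(1L) < profile$lapse) list(step = NA_real_, upper = NA)
        else accumulate_first(runif(1L, -profile$start_var * a, profile$start_var * a),
                              v$pre, round(v$misdir / dt), v$p_guess,
                              v$p_capture, a, max_steps, sigma, dt)
  if (is.na(go$step)) return(out)  # no go finish: trivially inhibited
  go_time <- go$step * dt + ter
  noise <- rnorm(1L, 0, profile$stop_latency_sd)
  stop_finish <- ssd + profile$stop_latency_mean + fe + noise
  if (stop_finish < go_time) return(out)  # stop wins: response inhibited
  out$responded <- TRUE
  out$success <- FALSE
  out$first_response_time <- go_time
  out$first_response_correct <- go$upper
  # release shares the trial's stop noise but is centred on the player's
  # release latency; it cannot precede the movement it releases, and a
  # release that would fall beyond the trial window is never observed
  release <- max(ssd + profile$release_latency_mean + fe + noise,
                 go_time + dt)
  if (release > go_window) return(out)
  out$release_time <- release
  if (runif(1L) < lava_correction_prob) {
    out$correction_after_release_time <-
      max(rnorm(1L, profile$correction_latency_mean, 40), 30)
  }
  out
}
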