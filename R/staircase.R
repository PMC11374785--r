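#' Adaptive staircase state and update rule
#'
#' The game adapts two quantities trial-by-trial. The stop-signal delay
#' (modes `"ssd_match"`, `"ssd_mismatch"`) moves in fixed 50 ms steps:
#' a response after the stop signal makes the lava appear 50 ms earlier
#' (delay decreases), a successful inhibition makes it appear 50 ms later.
#' Its stationary respond rate is therefore 50%. The response window (mode
#' `"go_window"`) moves asymmetrically: a success shortens the window by
#' `step_down`, a failure lengthens it by `step_up`; with
#' `step_up / step_down = p / (1 - p)` the stationary success rate is `p`
#' (4:1 for the 80% target). Values are floored at 0.
#'
#' @param mode One of `"go_window"`, `"ssd_match"`, `"ssd_mismatch"`.
#' @param value Current staircase value (ms).
#' @param step_up Increment applied when `outcome` is `FALSE` (go mode:
#'   failure; ssd modes: successful inhibition).
#' @param step_down Decrement applied when `outcome` is `TRUE` (go mode:
#'   success; ssd modes: response after the signal). For ssd modes both
#'   steps must equal the 50 ms staircase step.
#' @return `staircase_state()` returns a list of class `"staircase_state"`;
#'   `staircase_update()` returns the updated state.
#' @export
#' @examples
#' s <- staircase_state("ssd_match", 300)
#' staircase_update(s, TRUE)$current_value   # responded: 250
#' staircase_update(s, FALSE)$current_value  # inhibited: 350
staircase_state <- function(mode = c("go_window", "ssd_match", "ssd_mismatch"),
                            value, step_up = 50, step_down = 50) {
  mode <- match.arg(mode)
  if (!is.finite(value) || value < 0) stop("staircase value must be >= 0")
  if (step_up <= 0 || step_down <= 0) stop("staircase steps must be > 0")
  if (mode != "go_window" && step_up != step_down)
    stop("ssd staircases use equal up/down steps")
  structure(list(mode = mode, current_value = value,
                 step_up = step_up, step_down = step_down),
            class = "staircase_state")
}

#' @rdname staircase_state
#' @param state A `staircase_state`.
#' @param outcome Logical. For ssd modes, `TRUE` means the player responded
#'   (failed to inhibit); for the go-window mode, `TRUE` means the trial
#'   succeeded.
#' @export
staircase_update <- function(state, outcome) {
  if (!inherits(state, "staircase_state")) stop("state must be a staircase_state")
  if (!state$mode %in% c("go_window", "ssd_match", "ssd_mismatch"))
    stop("unknown staircase mode: ", state$mode)
  if (is.na(outcome)) return(state)
  delta <- if (isTRUE(outcome)) -state$step_down else state$step_up
  state$current_value <- max(state$current_value + delta, 0)
  state
}

# Derived asymmetric steps for the response-window staircase.
go_window_steps <- function(cfg) {
  down <- cfg$go_step_down
  up <- down * cfg$go_success_target / (1 - cfg$go_success_target)
  list(up = up, down = down)
}
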