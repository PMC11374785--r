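#' Long-format response-time table from a session log
#'
#' Turns non-lava test trials into the long format consumed by the
#' hierarchical models: one row per correct first response (RT1, the first
#' response time), one per incorrect first response (`"first_error"`, kept
#' separately so that the conflict effect on error-correcting responses can
#' be decomposed), and one per error-correcting response (RT2, the time
#' from the central colour assignment to the initiation of the reversal).
#' For corrections, `delay_ms` is the time since the initial response,
#' which the trial-level filters use.
#'
#' @param trials A trial log (one or more players).
#' @return Data.frame: `player_id`, `trial_index`, `flanker_mismatch`,
#'   `ice`, `response_type` (`first` / `first_error` / `correction`),
#'   `time`, `delay_ms`, `condition` (flanker-by-ice cell label).
#' @export
extract_response_table <- function(trials) {
  t0 <- trials[trials$phase == "test" & !trials$lava & trials$responded, , drop = FALSE]
  cond <- function(df) paste0(ifelse(df$flanker_mismatch, "mismatch", "match"),
                              ".", ifelse(df$ice, "ice", "noice"))
  mk <- function(df, type, time, delay) {
    if (!nrow(df)) return(NULL)
    data.frame(player_id = df$player_id, trial_index = df$trial_index,
               flanker_mismatch = df$flanker_mismatch, ice = df$ice,
               response_type = type, time = time, delay_ms = delay,
               condition = cond(df))
  }
  firsts <- t0[!is.na(t0$first_response_correct) & t0$first_response_correct, , drop = FALSE]
  errs <- t0[!is.na(t0$first_response_correct) & !t0$first_response_correct, , drop = FALSE]
  corr <- errs[!is.na(errs$reversal_time), , drop = FALSE]
  out <- rbind(
    mk(firsts, "first", firsts$first_response_time, NA_real_),
    mk(errs, "first_error", errs$first_response_time, NA_real_),
    mk(corr, "correction", corr$reversal_time,
       corr$reversal_time - corr$first_response_time)
  )
  if (is.null(out)) {
    out <- data.frame(player_id = integer(0), trial_index = integer(0),
                      flanker_mismatch = logical(0), ice = logical(0),
                      response_type = character(0), time = numeric(0),
                      delay_ms = numeric(0), condition = character(0))
  }
  out <- out[order(out$player_id, out$trial_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Time-to-stop observations from lava trials
#'
#' Time-to-stop (TTS) is the time between the stop signal and the release
#' of an ongoing initial response, emitted only when the release is
#' followed by a corrective response (which shows clear recognition of the
#' mistaken initial response): `TTS = release_time - ssd`.
#'
#' @param trials A trial log.
#' @return Data.frame: `player_id`, `trial_index`, `flanker_mismatch`,
#'   `response_type = "correction"`, `time` (TTS, ms), `delay_ms`
#'   (identical to `time`; the correction filter window applies to the time
#'   since the stop signal), `condition`.
#' @export
extract_tts_table <- function(trials) {
  lv <- trials[trials$phase == "test" & trials$lava & trials$responded &
                 !is.na(trials$release_time) &
                 !is.na(trials$correction_after_release_time), , drop = FALSE]
  tts <- lv$release_time - lv$ssd
  out <- data.frame(
    player_id = lv$player_id, trial_index = lv$trial_index,
    flanker_mismatch = lv$flanker_mismatch, ice = FALSE,
    response_type = "correction", time = tts, delay_ms = tts,
    condition = ifelse(lv$flanker_mismatch, "lava.mismatch", "lava.match")
  )
  out <- out[order(out$player_id, out$trial_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integration-method stop-signal reaction time
#'
#' Nonparametric SSRT estimator: the stop process is assumed to finish at
#' the go-RT distribution's respond-rate percentile. Non-responses in the
#' go-RT set are replaced by the maximum observed RT; go RTs are sorted
#' ascending and the RT at rank `ceiling(p * n)` (p the probability of
#' responding given a stop signal) minus the mean stop-signal delay gives
#' the SSRT.
#'
#' @param go_rts Numeric go RTs (ms); `NA` marks a non-response.
#' @param stop_trials Data.frame with columns `ssd` and `responded`
#'   (logical), one row per stop trial.
#' @return SSRT in ms.
#' @export
#' @examples
#' go <- seq(400, 580, by = 20)
#' st <- data.frame(ssd = rep(200, 10), responded = rep(c(TRUE, FALSE), 5))
#' ssrt_integration(go, st)  # 480 - 200 = 280
ssrt_integration <- function(go_rts, stop_trials) {
  if (!length(go_rts)) stop("go_rts must be non-empty")
  if (!nrow(stop_trials)) stop("no stop trials")
  p <- mean(stop_trials$responded)
  if (p == 0) stop("stop rate 0: SSRT undefined (no signal-respond trials)")
  if (p == 1) warning("respond rate 1: SSRT from the boundary rank (max go RT)")
  if (all(is.na(go_rts))) stop("go_rts contains no observed RTs")
  rts <- go_rts
  rts[is.na(rts)] <- max(rts, na.rm = TRUE)
  rts <- sort(rts, method = "radix")  # stable; ties keep input order
  rank <- min(ceiling(p * length(rts)), length(rts))
  rts[rank] - mean(stop_trials$ssd)
}

#' Per-player SSRT, TTS and composite inputs from a cohort log
#'
#' Computes the two integration-method SSRT sub-measures (separately per
#' flanker condition, each with a condition-matched go-RT reference set:
#' regular trials for the matching sub-measure, mismatching non-ice trials
#' for the mismatching one) and the player's mean time-to-stop. No
#' trial-level filtering is applied to the SSRT inputs.
#'
#' @param trials A trial log.
#' @param tts Optional pre-filtered TTS table; defaults to
#'   [extract_tts_table()] of `trials`.
#' @return Data.frame: `player_id`, `ssrt_match`, `ssrt_mismatch`,
#'   `tts_mean`, `n_stop_match`, `n_stop_mismatch`, `n_tts`, `stop_rate`.
#' @export
compute_ssrt_results <- function(trials, tts = NULL) {
  if (is.null(tts)) tts <- extract_tts_table(trials)
  test <- trials[trials$phase == "test", , drop = FALSE]
  ids <- sort(unique(test$player_id))
  rows <- lapply(ids, function(id) {
    s <- test[test$player_id == id, , drop = FALSE]
    one <- function(mis) {
      go <- s[!s$lava & !s$ice & s$flanker_mismatch == mis, , drop = FALSE]
      st <- s[s$lava & s$flanker_mismatch == mis, , drop = FALSE]
      go_rts <- ifelse(go$responded, go$first_response_time, NA_real_)
      est <- tryCatch(
        suppressWarnings(ssrt_integration(go_rts,
                                          data.frame(ssd = st$ssd,
                                                     responded = st$responded))),
        error = function(e) NA_real_)
      list(est = est, n = nrow(st))
    }
    m <- one(FALSE); mm <- one(TRUE)
    tt <- tts$time[tts$player_id == id]
    lv <- s[s$lava, , drop = FALSE]
    data.frame(player_id = id, ssrt_match = m$est, ssrt_mismatch = mm$est,
               tts_mean = if (length(tt)) mean(tt) else NA_real_,
               n_stop_match = m$n, n_stop_mismatch = mm$n, n_tts = length(tt),
               stop_rate = if (nrow(lv)) mean(!lv$responded) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average of z-transformed sub-measures
#'
#' Column-wise z-transform over the analysed cohort (SD with the n-1
#' convention), then the per-player mean. Supports the two-column
#' (first-response-only SSRT) and three-column (with time-to-stop)
#' composites.
#'
#' @param submeasures Numeric matrix or data.frame, players in rows, >= 2
#'   sub-measure columns.
#' @return Numeric vector of per-player composite scores (z units).
#' @export
composite_z_average <- function(submeasures) {
  m <- as.matrix(submeasures)
  if (ncol(m) < 2L) stop("need at least 2 sub-measure columns")
  sds <- apply(m, 2L, sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("zero-variance sub-measure column: z-transform undefined")
  z <- scale(m)
  rowMeans(z)
}
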