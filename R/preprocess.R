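#' Player-level exclusion scoring
#'
#' Applies the points-based data-quality rules to each player's test-phase
#' trials. Two points each for: mean frame rate below 35; first-response
#' accuracy no higher than 3 binomial standard errors from 0.5 (one-sided by
#' default, `sqrt(0.25/n)` over scored non-lava first responses); and
#' non-response on more than 10% of non-lava trials. One point each for:
#' lava stopping rate above 0.7 or below 0.3; correcting mistaken first
#' movements in under 30% of opportunities in non-lava trials; in under 30%
#' of opportunities in lava trials; non-response on more than 3% of non-lava
#' trials; and mean frame rate below 45. Two or more points exclude the
#' player.
#'
#' Opportunities to correct are trials with an incorrect first response
#' (non-lava) or with a post-signal response (lava); a correction is a
#' recorded reversal (non-lava) or a corrective response after the release
#' (lava).
#'
#' @param trials Trial log covering one or more players (see
#'   [simulate_session()]). Only test-phase trials are scored.
#' @param fps Optional per-player mean frame rate: a data.frame with
#'   `player_id` and `fps` columns, or a vector named by player id. When
#'   absent the frame-rate rules are skipped.
#' @param accuracy_rule `"one_sided"` (default) excludes accuracy at or
#'   below `0.5 + 3*SE`; `"two_sided"` excludes accuracy within 3 SE of 0.5
#'   in either direction.
#' @return A data.frame with one row per player: `player_id`, `points`,
#'   `triggered_rules` (semicolon-joined identifiers), `excluded`.
#' @export
score_player_exclusions <- function(trials, fps = NULL,
                                    accuracy_rule = c("one_sided", "two_sided")) {
  accuracy_rule <- match.arg(accuracy_rule)
  test <- trials[trials$phase == "test", , drop = FALSE]
  if (!nrow(test)) stop("no test-phase trials to score")
  fps_tab <- NULL
  if (!is.null(fps)) {
    fps_tab <- if (is.data.frame(fps)) setNames(fps$fps, fps$player_id)
               else fps
  }
  out <- lapply(split(test, test$player_id), function(s) {
    id <- s$player_id[1L]
    nl <- s[!s$lava, , drop = FALSE]
    lv <- s[s$lava, , drop = FALSE]
    rules <- character(0)
    pts <- 0L
    add <- function(hit, name, weight) {
      if (isTRUE(hit)) {
        rules <<- c(rules, name)
        pts <<- pts + weight
      }
    }
    pf <- if (!is.null(fps_tab)) unname(fps_tab[as.character(id)]) else NA_real_
    if (!is.na(pf)) {
      add(pf < 35, "fps_below_35", 2L)
      add(pf < 45, "fps_below_45", 1L)
    }
    scored <- nl$responded & !is.na(nl$first_response_correct)
    n_acc <- sum(scored)
    if (n_acc > 0L) {
      acc <- mean(nl$first_response_correct[scored])
      se3 <- 3 * sqrt(0.25 / n_acc)
      near_chance <- if (accuracy_rule == "one_sided") acc <= 0.5 + se3
                     else abs(acc - 0.5) <= se3
      add(near_chance, "accuracy_near_chance", 2L)
    }
    nr <- mean(!nl$responded)
    add(nr > 0.10, "nonresponse_over_10pct", 2L)
    add(nr > 0.03, "nonresponse_over_3pct", 1L)
    if (nrow(lv)) {
      stop_rate <- mean(!lv$responded)
      add(stop_rate > 0.7 || stop_rate < 0.3, "stop_rate_out_of_band", 1L)
      opp_lava <- lv$responded
      if (any(opp_lava)) {
        corr_lava <- mean(!is.na(lv$correction_after_release_time[opp_lava]))
        add(corr_lava < 0.30, "lava_correction_under_30pct", 1L)
      }
    }
    opp <- nl$responded & !is.na(nl$first_response_correct) & !nl$first_response_correct
    if (any(opp)) {
      corr <- mean(!is.na(nl$reversal_time[opp]))
      add(corr < 0.30, "nonlava_correction_under_30pct", 1L)
    }
    data.frame(player_id = id, points = pts,
               triggered_rules = paste(rules, collapse = ";"),
               excluded = pts >= 2L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trial-level filtering of measure observations
#'
#' Implements the two trial-level filter sets. `"rt1"` applies to first
#' responses: drop times below 300 ms or above 1500 ms, then drop times more
#' than 3 SD from the player's own mean per condition. `"correction"`
#' applies to error-correcting responses: drop corrections arriving more
#' than 1000 ms after the initial response (non-lava) or after the stop
#' signal (lava) -- the table's `delay_ms` column -- then the same per-player
#' per-condition 3 SD rule. SD rules are computed on the range-filtered set
#' and re-applied until no observation changes, which makes the whole
#' filter idempotent.
#' Rows whose response type does not match `rule_set` pass through untouched
#' and are not counted in the statistics. No trial-level filtering is ever
#' applied to the go and stop inputs of the SSRT integration method.
#'
#' @param observations A measure table (see [extract_response_table()] /
#'   [extract_tts_table()]) with columns `player_id`, `condition`,
#'   `response_type`, `time`, `delay_ms`.
#' @param rule_set `"rt1"` or `"correction"`.
#' @param range Range limits in ms (first responses: `c(300, 1500)`;
#'   corrections use `c(0, 1000)` on `delay_ms`).
#' @param sd_mult SD multiplier for the dispersion rule.
#' @return `list(table = filtered observations, stats = data.frame)` with
#'   per-player counts `n_input`, `n_removed_range`, `n_removed_sd`,
#'   `n_retained`.
#' @export
filter_trials <- function(observations, rule_set = c("rt1", "correction"),
                          range = NULL, sd_mult = 3) {
  rule_set <- match.arg(rule_set)
  first_types <- c("first", "first_error")
  sel <- if (rule_set == "rt1") observations$response_type %in% first_types
         else observations$response_type == "correction"
  keep_through <- observations[!sel, , drop = FALSE]
  tab <- observations[sel, , drop = FALSE]
  if (!nrow(tab)) {
    stats <- data.frame(player_id = integer(0), measure = character(0),
                        n_input = integer(0), n_removed_range = integer(0),
                        n_removed_sd = integer(0), n_retained = integer(0))
    return(list(table = observations, stats = stats))
  }
  if (rule_set == "rt1") {
    if (is.null(range)) range <- c(300, 1500)
    in_range <- tab$time >= range[1L] & tab$time <= range[2L]
  } else {
    if (is.null(range)) range <- c(0, 1000)
    in_range <- tab$delay_ms >= range[1L] & tab$delay_ms <= range[2L]
  }
  ranged <- tab[in_range, , drop = FALSE]
  # dispersion rule applied to a fixed point, so the filter is idempotent:
  # re-running it on its own output removes nothing further
  retained <- ranged
  removed_sd <- ranged[0L, , drop = FALSE]
  repeat {
    grp <- interaction(retained$player_id, retained$condition, drop = TRUE)
    mu <- ave(retained$time, grp, FUN = mean)
    s <- ave(retained$time, grp, FUN = sd)
    s[is.na(s)] <- 0
    keep_sd <- s == 0 | abs(retained$time - mu) <= sd_mult * s
    if (all(keep_sd)) break
    removed_sd <- rbind(removed_sd, retained[!keep_sd, , drop = FALSE])
    retained <- retained[keep_sd, , drop = FALSE]
  }
  counts <- function(df) table(factor(df$player_id, levels = unique(tab$player_id)))
  stats <- data.frame(
    player_id = unique(tab$player_id),
    measure = rule_set,
    n_input = as.integer(counts(tab)),
    n_removed_range = as.integer(counts(tab[!in_range, , drop = FALSE])),
    n_removed_sd = as.integer(counts(removed_sd)),
    n_retained = as.integer(counts(retained))
  )
  out <- rbind(keep_through, retained)
  out <- out[order(out$player_id, out$trial_index), , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, stats = stats)
}

#' Per-player measure eligibility flags
#'
#' A player enters the flanker (or ice) analyses only with at least
#' `min_corrections` retained error-correcting responses in each relevant
#' trial type: matching and mismatching flanker trials (non-ice) for the
#' flanker effect, ice and non-ice trials for the ice effect. The SSRT /
#' time-to-stop flag requires the lava stopping rate to lie within
#' `stop_range` (integration-method requirement) and at least
#' `min_corrections` time-to-stop observations.
#'
#' @param responses Filtered response table ([extract_response_table()]).
#' @param tts Filtered time-to-stop table ([extract_tts_table()]).
#' @param trials Trial log (test phase is used for lava stopping rates).
#' @param min_corrections Minimum retained corrections per trial type.
#' @param stop_range Allowed stopping-rate band.
#' @return Data.frame: `player_id`, `flanker`, `ice`, `ssrt_tts`.
#' @export
measure_eligibility <- function(responses, tts, trials,
                                min_corrections = 3L,
                                stop_range = c(0.30, 0.70)) {
  test <- trials[trials$phase == "test", , drop = FALSE]
  ids <- sort(unique(test$player_id))
  res <- lapply(ids, function(id) {
    rp <- responses[responses$player_id == id &
                      responses$response_type == "correction", , drop = FALSE]
    fl_ok <- sum(!rp$ice & !rp$flanker_mismatch) >= min_corrections &&
      sum(!rp$ice & rp$flanker_mismatch) >= min_corrections
    ice_ok <- sum(rp$ice) >= min_corrections && sum(!rp$ice) >= min_corrections
    lv <- test[test$player_id == id & test$lava, , drop = FALSE]
    stop_rate <- if (nrow(lv)) mean(!lv$responded) else NA_real_
    n_tts <- sum(tts$player_id == id)
    ssrt_ok <- !is.na(stop_rate) && stop_rate >= stop_range[1L] &&
      stop_rate <= stop_range[2L] && n_tts >= min_corrections
    data.frame(player_id = id, flanker = fl_ok, ice = ice_ok, ssrt_tts = ssrt_ok)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
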