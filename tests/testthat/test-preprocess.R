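# Player-level exclusion scoring and trial-level filters, exercised on
# hand-built trial logs where every rate is controlled exactly.

# a player with the given non-lava accuracy, lava stopping rate and
# correction behaviour over a controllable number of trials
synthetic_player <- function(id, n_nonlava = 200, accuracy = 0.9,
                             nonresponse = 0, correct_rate = 0.8,
                             n_lava = 84, stop_rate = 0.5,
                             lava_correct_rate = 0.8) {
  n_resp <- round(n_nonlava * (1 - nonresponse))
  n_acc <- round(n_resp * accuracy)
  n_err <- n_resp - n_acc
  n_corr <- round(n_err * correct_rate)
  nl <- make_trial(id, seq_len(n_nonlava),
                   responded = rep(c(TRUE, FALSE), c(n_resp, n_nonlava - n_resp)),
                   first_response_time = 500,
                   first_response_correct = rep(c(TRUE, FALSE, NA),
                                                c(n_acc, n_err, n_nonlava - n_resp)),
                   reversal_time = rep(c(NA, 800, NA),
                                       c(n_acc, n_corr, n_nonlava - n_acc - n_corr)),
                   success = TRUE)
  nl$first_response_time[!nl$responded] <- NA
  n_go <- round(n_lava * stop_rate)       # inhibited trials
  n_move <- n_lava - n_go
  n_lcorr <- round(n_move * lava_correct_rate)
  lv <- make_trial(id, n_nonlava + seq_len(n_lava), lava = TRUE, ssd = 250,
                   responded = rep(c(FALSE, TRUE), c(n_go, n_move)),
                   first_response_time = rep(c(NA, 450), c(n_go, n_move)),
                   first_response_correct = rep(c(NA, TRUE), c(n_go, n_move)),
                   release_time = rep(c(NA, 520), c(n_go, n_move)),
                   correction_after_release_time =
                     rep(c(NA, 180, NA), c(n_go, n_lcorr, n_move - n_lcorr)),
                   success = rep(c(TRUE, FALSE), c(n_go, n_move)))
  rbind(nl, lv)
}

test_that("single two-point rules exclude a player on their own", {
  tr <- synthetic_player(1)
  # low frame rate alone: 2 points
  rep1 <- score_player_exclusions(tr, fps = c("1" = 30))
  expect_equal(rep1$points, 3L)  # fps<35 (2) also trips fps<45 (1)
  expect_true(rep1$excluded)
  expect_match(rep1$triggered_rules, "fps_below_35")
  # near-chance accuracy alone
  rep2 <- score_player_exclusions(synthetic_player(1, accuracy = 0.5),
                                  fps = c("1" = 60))
  expect_true(rep2$excluded)
  expect_match(rep2$triggered_rules, "accuracy_near_chance")
  # heavy non-response alone
  rep3 <- score_player_exclusions(synthetic_player(1, nonresponse = 0.15),
                                  fps = c("1" = 60))
  expect_true(rep3$excluded)
  expect_match(rep3$triggered_rules, "nonresponse_over_10pct")
})

test_that("one-point rules only exclude in combination", {
  # out-of-band stopping rate alone: 1 point, retained
  r1 <- score_player_exclusions(synthetic_player(1, stop_rate = 0.25),
                                fps = c("1" = 60))
  expect_equal(r1$points, 1L)
  expect_false(r1$excluded)
  expect_match(r1$triggered_rules, "stop_rate_out_of_band")
  # plus a low non-lava correction rate: 2 points, excluded
  r2 <- score_player_exclusions(
    synthetic_player(1, stop_rate = 0.25, correct_rate = 0.2),
    fps = c("1" = 60))
  expect_equal(r2$points, 2L)
  expect_true(r2$excluded)
  # low lava correction rate is its own point
  r3 <- score_player_exclusions(
    synthetic_player(1, lava_correct_rate = 0.2), fps = c("1" = 60))
  expect_equal(r3$points, 1L)
  expect_match(r3$triggered_rules, "lava_correction_under_30pct")
})

test_that("accuracy rule sidedness is configurable and scoring needs data", {
  perfect_low <- synthetic_player(1, accuracy = 0.35)
  one <- score_player_exclusions(perfect_low, fps = c("1" = 60))
  expect_true(one$excluded)  # below chance is near-chance one-sided
  two <- score_player_exclusions(perfect_low, fps = c("1" = 60),
                                 accuracy_rule = "two_sided")
  expect_false(grepl("accuracy_near_chance", two$triggered_rules))
  expect_error(score_player_exclusions(make_trial(phase = "training")),
               "test-phase")
})

test_that("range filters drop the printed trial-level outliers", {
  tab <- data.frame(
    player_id = 1L, trial_index = 1:6,
    flanker_mismatch = FALSE, ice = FALSE,
    response_type = c("first", "first", "first", "correction", "correction",
                      "correction"),
    time = c(250, 500, 1600, 700, 900, 950),
    delay_ms = c(NA, NA, NA, 1200, 400, 420),
    condition = "match.noice")
  r1 <- filter_trials(tab, "rt1")
  expect_equal(sum(r1$table$response_type == "first"), 1L)  # 250 and 1600 dropped
  expect_equal(r1$stats$n_removed_range, 2L)
  r2 <- filter_trials(r1$table, "correction")
  expect_equal(sum(r2$table$response_type == "correction"), 2L)  # 1200 ms delay dropped
  # rows of the other response type pass through untouched
  expect_equal(sum(r2$table$response_type == "first"), 1L)
})

test_that("the per-player dispersion rule is inert for constant times", {
  tab <- data.frame(player_id = 1L, trial_index = 1:20,
                    flanker_mismatch = FALSE, ice = FALSE,
                    response_type = "first", time = 600, delay_ms = NA,
                    condition = "match.noice")
  out <- filter_trials(tab, "rt1")
  expect_equal(out$stats$n_removed_sd, 0L)
  expect_equal(out$stats$n_retained, 20L)
})

test_that("filtering is idempotent and the SD rule only removes trials", {
  resp <- shared_measures()$responses  # already filtered once
  again <- filter_trials(filter_trials(resp, "rt1")$table, "correction")$table
  expect_equal(nrow(again), nrow(resp))
  expect_equal(again$time, resp$time)

  raw <- extract_response_table(shared_cohort()$trials)
  with_sd <- filter_trials(raw, "rt1", sd_mult = 3)
  without_sd <- filter_trials(raw, "rt1", sd_mult = Inf)
  expect_true(all(without_sd$stats$n_retained >= with_sd$stats$n_retained))
  expect_equal(with_sd$stats$n_input,
               with_sd$stats$n_removed_range + with_sd$stats$n_removed_sd +
                 with_sd$stats$n_retained)
})

test_that("clean cohorts trigger no frame-rate or non-response rules", {
  pop <- population_params(lapse_mean = 0, lapse_sd = 0,
                           fps_mean = 60, fps_sd = 2)
  coh <- simulate_cohort(pop, 6, game_config(), seed = 77)
  rep <- score_player_exclusions(coh$trials, coh$truth[, c("player_id", "fps")])
  rules <- unlist(strsplit(rep$triggered_rules, ";"))
  expect_false(any(grepl("fps|nonresponse", rules)))
})

test_that("measure eligibility applies the three-corrections and stop-rate rules", {
  m <- shared_measures()
  elig <- measure_eligibility(m$responses, m$tts, m$trials)
  expect_true(all(c("flanker", "ice", "ssrt_tts") %in% names(elig)))
  # recompute one flag by hand for every player
  for (id in elig$player_id) {
    rp <- m$responses[m$responses$player_id == id &
                        m$responses$response_type == "correction", ]
    by_hand <- sum(!rp$ice & !rp$flanker_mismatch) >= 3 &&
      sum(!rp$ice & rp$flanker_mismatch) >= 3
    expect_equal(elig$flanker[elig$player_id == id], by_hand)
  }
  # a stopping rate just outside the band blocks the SSRT flag
  tr <- synthetic_player(9, stop_rate = 0.28)
  resp <- extract_response_table(tr)
  tts <- extract_tts_table(tr)
  e <- measure_eligibility(resp, tts, tr)
  expect_false(e$ssrt_tts)
})
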