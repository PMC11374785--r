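test_that("the response table maps trials to RT1/RT2 rows", {
  tr <- rbind(
    make_trial(1, 1, first_response_time = 520),                 # correct first
    make_trial(1, 2, first_response_time = 450,                  # corrected error
               first_response_correct = FALSE, reversal_time = 700),
    make_trial(1, 3, responded = FALSE, first_response_time = NA,
               first_response_correct = NA, success = FALSE),    # non-response
    make_trial(1, 4, first_response_time = 480,                  # uncorrected error
               first_response_correct = FALSE, success = FALSE),
    make_trial(1, 5, lava = TRUE, ssd = 300, first_response_time = 430,
               release_time = 520, correction_after_release_time = 180,
               success = FALSE)                                  # lava: not RT1/RT2
  )
  tab <- extract_response_table(tr)
  first <- tab[tab$response_type == "first", ]
  expect_equal(first$time, 520)
  corr <- tab[tab$response_type == "correction", ]
  expect_equal(corr$time, 700)
  expect_equal(corr$delay_ms, 250)
  errs <- tab[tab$response_type == "first_error", ]
  expect_setequal(errs$time, c(450, 480))
  expect_false(5 %in% tab$trial_index)   # lava trials never enter
  expect_false(3 %in% tab$trial_index)   # non-responses leave no rows
})

test_that("time-to-stop is release minus ssd, only with a corrective response", {
  tr <- rbind(
    make_trial(1, 1, lava = TRUE, ssd = 300, first_response_time = 430,
               release_time = 520, correction_after_release_time = 170,
               success = FALSE),
    make_trial(1, 2, lava = TRUE, ssd = 300, first_response_time = 430,
               release_time = 600, success = FALSE),     # no corrective response
    make_trial(1, 3, lava = TRUE, ssd = 250, responded = FALSE,
               first_response_time = NA, first_response_correct = NA)  # inhibited
  )
  tts <- extract_tts_table(tr)
  expect_equal(nrow(tts), 1L)
  expect_equal(tts$time, 220)
})

test_that("integration-method SSRT matches the hand-ranked oracle", {
  # 10 go RTs 400..580, respond rate 0.5, mean SSD 200:
  # rank ceiling(0.5*10)=5 -> 480; SSRT = 480 - 200 = 280
  go <- seq(400, 580, by = 20)
  st <- data.frame(ssd = rep(200, 10), responded = rep(c(TRUE, FALSE), 5))
  expect_equal(ssrt_integration(go, st), 280)

  # respond rate 1: boundary rank is the maximum go RT
  st1 <- data.frame(ssd = rep(200, 4), responded = TRUE)
  expect_warning(out <- ssrt_integration(go, st1), "boundary rank")
  expect_equal(out, 580 - 200)

  # non-responses replaced by the maximum observed RT: nine RTs of 500 and
  # one omission at respond rate 0.9 put rank 9 at 500
  go2 <- c(rep(500, 9), NA)
  st2 <- data.frame(ssd = rep(180, 10), responded = c(rep(TRUE, 9), FALSE))
  expect_equal(ssrt_integration(go2, st2), 500 - 180)

  st0 <- data.frame(ssd = rep(200, 4), responded = FALSE)
  expect_error(ssrt_integration(go, st0), "stop rate 0")
  expect_error(ssrt_integration(numeric(0), st1), "non-empty")
})

test_that("z-composites behave like standardised averages", {
  m <- cbind(a = c(1, 3, 5, 7), b = c(1, 3, 5, 7))
  comp <- composite_z_average(m)
  expect_equal(comp, as.numeric(scale(m[, 1])))
  # location shifts of one column leave the composite unchanged
  m2 <- m; m2[, 2] <- m2[, 2] + 100
  expect_equal(composite_z_average(m2), comp)
  # two players, values {1, 3}: z = -/+ 1/sqrt(2) under the n-1 convention
  z <- composite_z_average(cbind(c(1, 3), c(1, 3)))
  expect_equal(z, c(-1, 1) / sqrt(2))
  expect_error(composite_z_average(cbind(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance")
})

test_that("error corrections take longer than correct first responses", {
  resp <- shared_measures()$responses
  per_player <- split(resp, resp$player_id)
  cmp <- vapply(per_player, function(s) {
    rt1 <- s$time[s$response_type == "first"]
    rt2 <- s$time[s$response_type == "correction"]
    if (length(rt2) < 8) return(NA) else mean(rt2) > mean(rt1)
  }, logical(1))
  expect_true(all(cmp, na.rm = TRUE))
})

test_that("per-player time-to-stop recovers the generative stop latency", {
  m <- shared_measures()
  coh <- shared_cohort()
  per <- aggregate(time ~ player_id, data = m$tts, FUN = mean)
  per <- merge(per, coh$truth[, c("player_id", "release_latency_mean",
                                  "stop_latency_mean")])
  per <- per[table(m$tts$player_id)[as.character(per$player_id)] >= 20, ]
  # pooled bias small relative to the within-player noise
  expect_lt(abs(mean(per$time - per$release_latency_mean)), 15)
  expect_gt(cor(per$time, per$release_latency_mean), 0.85)
})

test_that("integration SSRT tracks the generative stop latency across players", {
  m <- shared_measures()
  ssrt <- compute_ssrt_results(m$trials, m$tts)
  ssrt <- ssrt[ssrt$stop_rate >= 0.3 & ssrt$stop_rate <= 0.7 &
                 complete.cases(ssrt[, c("ssrt_match", "ssrt_mismatch")]), ]
  both <- merge(ssrt, shared_cohort()$truth[, c("player_id", "stop_latency_mean")])
  est <- (both$ssrt_match + both$ssrt_mismatch) / 2
  expect_gt(cor(est, both$stop_latency_mean), 0.6)
  expect_lt(abs(mean(est - both$stop_latency_mean)), 40)
})
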