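# Hierarchical conflict-effect models: recovery against the Gaussian
# generator (whose truth is exact), per-player effects, precision, and the
# effect-comparison statistics.

test_that("model variants build the intended random-effect structures", {
  d <- simulate_measure_table(12, n_first = c(30, 30), n_correction = c(8, 8),
                              seed = 1)
  mj <- suppressMessages(conflict_model(d, "maximal_joint"))
  expect_setequal(colnames(lme4::ranef(mj$fit)$player),
                  c("(Intercept)", "conflict", "response", "conflict:response"))
  sc <- suppressMessages(conflict_model(d, "shared_conflict"))
  expect_setequal(colnames(lme4::ranef(sc$fit)$player),
                  c("(Intercept)", "conflict", "response"))
  tm <- suppressMessages(conflict_model(d, "tts_model"))
  expect_equal(colnames(lme4::ranef(tm$fit)$player), "(Intercept)")
  expect_error(conflict_model(d[, c("player_id", "time")], "maximal_joint"),
               "lacks column")
  expect_error(conflict_model(d[d$player_id == 1, ], "single_response"),
               "at least 2 players")
})

test_that("a known 50 ms conflict effect is recovered", {
  d <- simulate_measure_table(60, n_first = c(90, 90), n_correction = c(14, 14),
                              beta = c(500, 50, 150, 0),
                              sd_random = c(60, 30, 40, 0), sigma = 120,
                              seed = 202)
  fit <- suppressMessages(conflict_model(d, "shared_conflict"))
  ci <- cr2_inference(fit, "conflict")
  expect_lt(abs(ci$estimate - 50), 3 * ci$se)
  expect_lt(ci$p, 0.001)
})

test_that("random-slope SD of 30 ms is recovered to the stated band", {
  d <- simulate_measure_table(80, n_first = c(90, 90), n_correction = c(0, 0),
                              beta = c(500, 50, 0, 0),
                              sd_random = c(60, 30, 0, 0), sigma = 120,
                              seed = 203)
  fit <- suppressMessages(conflict_model(d, "single_response"))
  sds <- attr(lme4::VarCorr(fit$fit)$player, "stddev")
  expect_gt(sds[["conflict"]], 20)
  expect_lt(sds[["conflict"]], 40)
})

test_that("null conflict effects stay inside their confidence intervals", {
  covered <- vapply(1:25, function(k) {
    d <- simulate_measure_table(25, n_first = c(40, 40), n_correction = c(0, 0),
                                beta = c(500, 0, 0, 0),
                                sd_random = c(50, 20, 0, 0), sigma = 100,
                                seed = 7000 + k)
    fit <- suppressMessages(conflict_model(d, "single_response"))
    ci <- cr2_inference(fit, "conflict")
    ci$ci[1] <= 0 && 0 <= ci$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.84)
})

test_that("conditional modes shrink toward the fixed effect", {
  d <- simulate_measure_table(40, n_first = c(25, 25), n_correction = c(6, 6),
                              seed = 11)
  fit <- suppressMessages(conflict_model(d, "maximal_joint"))
  eb <- player_effects(fit, "conditional")
  np <- player_effects(fit, "no_pooling")
  fe <- coef(fit)[["conflict"]]
  expect_lt(mean(abs(eb$effect_rt1 - fe)), mean(abs(np$effect_rt1 - fe)))
})

test_that("with identical players the conditional modes vanish", {
  d <- simulate_measure_table(20, n_first = c(60, 60), n_correction = c(10, 10),
                              beta = c(500, 50, 150, 10),
                              sd_random = c(0, 0, 0, 0), sigma = 80, seed = 12)
  fit <- suppressMessages(conflict_model(d, "maximal_joint"))
  eb <- player_effects(fit)
  expect_lt(sd(eb$effect_rt1), 5)
  expect_lt(abs(mean(eb$effect_rt1) - 50), 10)
})

test_that("in the small-noise limit conditional modes equal per-player OLS", {
  d <- simulate_measure_table(15, n_first = c(40, 40), n_correction = c(12, 12),
                              beta = c(500, 50, 150, 20),
                              sd_random = c(40, 25, 20, 15), sigma = 1,
                              seed = 13)
  fit <- suppressMessages(conflict_model(d, "maximal_joint"))
  eb <- player_effects(fit, "conditional")
  np <- player_effects(fit, "no_pooling")
  expect_lt(max(abs(eb$effect_rt1 - np$effect_rt1)), 1)
  expect_lt(max(abs(eb$effect_rt2 - np$effect_rt2)), 1)
})

test_that("precision eta is the slope-to-residual SD ratio", {
  d <- simulate_measure_table(80, n_first = c(70, 70), n_correction = c(0, 0),
                              beta = c(500, 50, 0, 0),
                              sd_random = c(60, 60, 0, 0), sigma = 120,
                              seed = 204)
  fit <- suppressMessages(conflict_model(d, "single_response"))
  eta <- precision_eta(fit, "conflict")
  expect_gt(eta, 0.35); expect_lt(eta, 0.65)
  # no individual differences: eta collapses toward zero
  d0 <- simulate_measure_table(40, n_first = c(40, 40), n_correction = c(0, 0),
                               sd_random = c(50, 0, 0, 0), sigma = 100,
                               seed = 205)
  fit0 <- suppressMessages(conflict_model(d0, "single_response"))
  expect_lt(precision_eta(fit0, "conflict"), 0.1)
  expect_error(precision_eta(fit0, "intercept"), NA)
})

test_that("effect correlations report r, t with df = n-2, and a Fisher CI", {
  x <- rnorm(85)
  r1 <- correlate_effects(x, x)
  expect_equal(r1$r, 1)
  r2 <- correlate_effects(x, x + rnorm(85))
  expect_equal(r2$df, 83)
  expect_true(r2$ci[1] <= r2$r && r2$r <= r2$ci[2])
  null_r <- with_seed_test(31, correlate_effects(rnorm(1000), rnorm(1000)))
  expect_lt(abs(null_r$r), 0.08)
  expect_error(correlate_effects(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("paired comparisons use df = n-1 and flag degenerate inputs", {
  x <- rnorm(97); y <- x + rnorm(97)
  out <- paired_t(x, y)
  expect_equal(out$df, 96)
  same <- paired_t(x, x)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "degenerate")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("model methods print, predict, simulate and plot", {
  d <- simulate_measure_table(10, n_first = c(20, 20), n_correction = c(5, 5),
                              seed = 14)
  fit <- suppressMessages(conflict_model(d, "shared_conflict"))
  expect_output(print(fit), "shared_conflict")
  expect_length(coef(fit), 4L)
  expect_equal(length(predict(fit)), fit$n_obs)
  expect_equal(length(residuals(fit)), fit$n_obs)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(fit$n_obs, 2L))
  s <- summary(fit)
  expect_s3_class(s, "summary.conflict_model")
  expect_true(all(c("estimate", "se", "df", "p") %in% names(s$fixed)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
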