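# Split-half reliability, McDonald's omega, the BCa bootstrap and the
# trial-translation mapping.

test_that("split-half reliability is 1 for deterministic scores and ~0 for noise", {
  tab <- data.frame(player_id = rep(1:40, each = 20),
                    condition = "c", trial_index = rep(1:20, 40),
                    value = rep(1:40, each = 20))
  ident <- function(half) data.frame(player_id = unique(half$player_id),
                                     score = unique(half$player_id))
  out <- split_half_reliability(tab, ident)
  expect_equal(out$r_split, 1)
  expect_equal(out$r_corrected, 1)

  noise <- function(half) {
    agg <- aggregate(value ~ player_id, half, mean)
    data.frame(player_id = agg$player_id, score = rnorm(nrow(agg)))
  }
  tab2 <- data.frame(player_id = rep(1:200, each = 4), condition = "c",
                     trial_index = rep(1:4, 200), value = 0)
  out2 <- with_seed_test(3, split_half_reliability(tab2, noise))
  expect_lt(abs(out2$r_corrected), 0.2)
})

test_that("Spearman-Brown corrected halves match the analytic reliability", {
  # known mixture: score = true (var 1) + trial error (var 9), 40 trials
  n <- 300; k <- 40; vt <- 1; ve <- 9
  tab <- with_seed_test(17, {
    truth <- rnorm(n, 0, sqrt(vt))
    data.frame(player_id = rep(seq_len(n), each = k), condition = "c",
               trial_index = rep(seq_len(k), n),
               value = rep(truth, each = k) + rnorm(n * k, 0, sqrt(ve)))
  })
  score <- function(half) {
    agg <- aggregate(value ~ player_id, half, mean)
    names(agg)[2] <- "score"
    agg
  }
  out <- split_half_reliability(tab, score)
  expected <- vt / (vt + ve / k)   # reliability of the full-length mean
  expect_lt(abs(out$r_corrected - expected), 0.07)
})

test_that("omega follows the closed-form single-factor solutions", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  expect_equal(changeofmind:::omega_from_cor(R), 0.75)
  # two indicators under equal loadings
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(changeofmind:::omega_from_cor(R2),
               (2 * sqrt(0.6))^2 / ((2 * sqrt(0.6))^2 + 2 * 0.4))
  # simulated factor model with loadings 0.7
  dat <- with_seed_test(19, {
    f <- rnorm(500)
    sapply(1:3, function(i) 0.7 * f + sqrt(1 - 0.49) * rnorm(500))
  })
  expect_lt(abs(mcdonalds_omega(dat) - 0.742), 0.05)
  # perfectly correlated and uncorrelated indicators
  x <- rnorm(100)
  expect_equal(mcdonalds_omega(cbind(x, x, x)), 1)
  un <- with_seed_test(20, cbind(rnorm(400), rnorm(400), rnorm(400)))
  expect_lt(mcdonalds_omega(un), 0.35)
  expect_error(mcdonalds_omega(cbind(x, -x)), "incoherent")
})

test_that("the BCa interval reduces to the percentile interval at z0 = a = 0", {
  theta_star <- rnorm(5000)
  got <- changeofmind:::bca_interval(theta_star, z0 = 0, a = 0)
  plain <- unname(quantile(theta_star, c(0.025, 0.975), type = 6))
  expect_equal(got, plain)
})

test_that("BCa on a symmetric statistic has small bias correction", {
  x <- with_seed_test(23, rnorm(60))
  out <- bca_ci(mean, x, B = 1500, seed = 9)
  expect_lt(abs(out$z0), 0.15)
  expect_true(out$lo < out$estimate && out$estimate < out$hi)
  # reproducible bit-for-bit under a fixed seed
  out2 <- bca_ci(mean, x, B = 1500, seed = 9)
  expect_identical(out[c("lo", "hi", "z0", "a")], out2[c("lo", "hi", "z0", "a")])
})

test_that("BCa endpoints agree with the reference implementation", {
  skip_if_not_installed("boot")
  x <- with_seed_test(29, rexp(50))   # skewed so z0 and a matter
  ours <- bca_ci(mean, x, B = 6000, seed = 77)
  set.seed(77)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 6000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  scale <- sd(x) / sqrt(length(x))
  expect_lt(abs(ours$lo - ref[1]), 0.2 * scale)
  expect_lt(abs(ours$hi - ref[2]), 0.2 * scale)
})

test_that("cluster resampling respects the player structure", {
  df <- data.frame(player_id = rep(1:30, each = 5), v = rep(rnorm(30), each = 5))
  stat <- function(d) {
    # within-player constancy must survive resampling
    stopifnot(all(tapply(d$v, d$player_id, function(z) length(unique(z))) == 1))
    mean(tapply(d$v, d$player_id, mean))
  }
  out <- bca_ci(stat, df, B = 300, seed = 4)
  expect_equal(out$n_failed, 0L)
})

test_that("reliability increments translate through the trial-count mapping", {
  expect_equal(trial_equivalent_gain(0.6, 0.6), 0.5)
  m1 <- trial_equivalent_gain(0.732, 0.754)
  m2 <- trial_equivalent_gain(0.732, 0.80)
  expect_gt(m2, m1)
  expect_gt(m1, 0.5)
  expect_error(trial_equivalent_gain(0.8, 0.7), "no gain")
  expect_error(trial_equivalent_gain(0, 0.5), "reliabilities")
})

test_that("identical nested measures give a zero reliability difference everywhere", {
  out <- nested_bootstrap_validity_sim(n_players = 30, n_trials_a = 20,
                                       n_extra = 0, shared = TRUE,
                                       n_cohorts = 4, B = 60, seed = 6)
  expect_equal(out$details$rel_a, out$details$rel_b)
  expect_true(all(out$details$boot_sd_diff == 0))
})

test_that("independent measures: bootstrap SD of the difference tracks the truth", {
  out <- nested_bootstrap_validity_sim(n_players = 80, n_trials_a = 30,
                                       n_extra = 10, shared = FALSE,
                                       n_cohorts = 40, B = 250, seed = 8)
  expect_lt(abs(out$boot_sd_diff - out$true_sd_diff),
            0.5 * out$true_sd_diff)
  # under shared trials the bootstrap misjudges the coupling of the two
  # reliabilities; report point differences only (no CI) in that regime
  shared <- nested_bootstrap_validity_sim(n_players = 80, n_trials_a = 30,
                                          n_extra = 10, shared = TRUE,
                                          n_cohorts = 40, B = 250, seed = 8)
  expect_gt(shared$true_cor, out$true_cor)
})
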