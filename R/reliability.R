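#' Even-odd split-half reliability
#'
#' Splits each player's trials into halves by the within-condition parity
#' of the trial index (odd-ranked vs even-ranked trials of each
#' player-by-condition-by-response-type cell), computes the measurement on
#' each half with `score_fn`, correlates the halves across players, and
#' applies the Spearman-Brown correction to full length. Players for whom
#' either half-measure is undefined are dropped (the count is reported).
#'
#' @param tab Long observation table with `player_id`, `condition`,
#'   `response_type` (optional), `trial_index`, and whatever columns
#'   `score_fn` needs.
#' @param score_fn Function mapping a half-table to a data.frame with
#'   columns `player_id` and `score`.
#' @return List: `r_split` (raw half correlation), `r_corrected`
#'   (Spearman-Brown), `n_players`, `n_dropped`.
#' @export
split_half_reliability <- function(tab, score_fn) {
  cols <- intersect(c("player_id", "condition", "response_type"), names(tab))
  grp <- interaction(tab[cols], drop = TRUE)
  ord <- order(grp, tab$trial_index)
  rank_in_grp <- ave(seq_along(grp)[ord], grp[ord], FUN = seq_along)
  parity <- integer(nrow(tab))
  parity[ord] <- rank_in_grp %% 2L
  odd <- score_fn(tab[parity == 1L, , drop = FALSE])
  even <- score_fn(tab[parity == 0L, , drop = FALSE])
  m <- merge(odd, even, by = "player_id", suffixes = c("_odd", "_even"))
  ok <- complete.cases(m$score_odd, m$score_even)
  n_all <- length(unique(tab$player_id))
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 3L) stop("too few players with defined half-measures")
  r <- cor(m$score_odd, m$score_even)
  list(r_split = r, r_corrected = 2 * r / (1 + r),
       n_players = nrow(m), n_dropped = n_all - nrow(m))
}

# Model-based per-player conflict-effect scorer used by the split-half
# wrappers: fits the requested variant on the half-table and returns the
# empirical-Bayes per-player effects.
conflict_score_fn <- function(variant) {
  function(half) {
    d <- data.frame(time = half$time, player_id = half$player_id,
                    conflict = as.numeric(half$conflict),
                    response = as.numeric(half$response))
    fit <- conflict_model(d, variant)
    ef <- player_effects(fit)
    data.frame(player_id = ef$player_id, score = ef$effect_rt1)
  }
}

#' Split-half reliability of a conflict-effect measurement
#'
#' Computes the even-odd split-half reliability of the flanker or ice
#' effect for one cohort, either from first responses only (variant
#' `"first_only"`, a random-slope model on correct first responses) or
#' combining first and error-correcting responses (variant `"combined"`,
#' the shared-conflict joint model in which conflict-effect individual
#' differences are shared between response types). The hierarchical model
#' is refitted on each half.
#'
#' @param responses Filtered response table ([extract_response_table()]),
#'   already restricted to eligible players.
#' @param conflict `"flanker"` or `"ice"`.
#' @param variant `"first_only"` or `"combined"`.
#' @return As [split_half_reliability()].
#' @export
reliability_conflict_effect <- function(responses,
                                        conflict = c("flanker", "ice"),
                                        variant = c("first_only", "combined")) {
  conflict <- match.arg(conflict)
  variant <- match.arg(variant)
  tab <- conflict_model_data(responses, conflict,
                             include_corrections = variant == "combined")
  score <- conflict_score_fn(if (variant == "combined") "shared_conflict"
                             else "single_response")
  split_half_reliability(tab, score)
}

# Shape a response table into model data for one conflict type.
# flanker: non-ice trials, conflict = mismatching flankers.
# ice: conflict = ice trials (flanker conditions pooled).
conflict_model_data <- function(responses, conflict = c("flanker", "ice"),
                                include_corrections = TRUE,
                                response_types = NULL) {
  conflict <- match.arg(conflict)
  tab <- if (conflict == "flanker") {
    responses[!responses$ice, , drop = FALSE]
  } else {
    responses
  }
  if (is.null(response_types)) {
    response_types <- if (include_corrections) c("first", "correction") else "first"
  }
  tab <- tab[tab$response_type %in% response_types, , drop = FALSE]
  data.frame(player_id = tab$player_id, trial_index = tab$trial_index,
             conflict = as.numeric(if (conflict == "flanker") tab$flanker_mismatch
                                   else tab$ice),
             response = as.numeric(tab$response_type == "correction"),
             time = tab$time, condition = tab$condition,
             response_type = tab$response_type)
}

#' McDonald's omega for a z-composite
#'
#' Single-factor composite reliability
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)` for the average
#' of standardized sub-measures. With three indicators the one-factor model
#' is just-identified and solved in closed form from the correlation
#' matrix (`lambda_i = sqrt(r_ij * r_ik / r_jk)`); with two indicators an
#' equal-loadings constraint identifies `lambda = sqrt(r_12)`.
#'
#' @param indicators Numeric matrix or data.frame (players x k, k = 2 or
#'   3); rows with missing values are dropped.
#' @return Omega in `[0, 1]`.
#' @export
#' @examples
#' # three indicators with all pairwise correlations 0.5 give omega 0.75
mcdonalds_omega <- function(indicators) {
  m <- as.matrix(indicators)
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (!k %in% c(2L, 3L)) stop("omega supports 2 or 3 indicators")
  R <- cor(m)
  omega_from_cor(R)
}

omega_from_cor <- function(R) {
  k <- ncol(R)
  if (k == 2L) {
    r <- R[1L, 2L]
    if (r < 0) stop("negative inter-indicator correlation: composite incoherent")
    lam <- rep(sqrt(r), 2L)
  } else {
    r12 <- R[1L, 2L]; r13 <- R[1L, 3L]; r23 <- R[2L, 3L]
    prods <- c(r12 * r13 / r23, r12 * r23 / r13, r13 * r23 / r12)
    if (any(!is.finite(prods)) || any(prods < 0))
      stop("loading solution not positive: composite incoherent")
    lam <- sqrt(prods)
    if (any(lam > 1)) lam <- pmin(lam, 1)  # Heywood guard
  }
  theta <- 1 - lam^2
  sum(lam)^2 / (sum(lam)^2 + sum(theta))
}

#' BCa bootstrap confidence interval over players
#'
#' Bias-corrected and accelerated bootstrap for a between-player statistic.
#' The resampling unit is the player (cluster bootstrap): each iteration
#' resamples player ids with replacement and evaluates `stat_fn` on the
#' corresponding rows. The bias correction `z0` is the normal quantile of
#' the bootstrap proportion below the point estimate; the acceleration `a`
#' comes from the jackknife-over-players skewness. With `z0 = a = 0` the
#' interval reduces to the plain percentile interval.
#'
#' @param stat_fn Function: data subset -> scalar statistic.
#' @param data Data.frame with a `player_id` column, or a plain vector
#'   (then elements are the resampling units).
#' @param B Bootstrap iterations (>= 100).
#' @param seed Optional seed.
#' @param level Confidence level.
#' @return List: `estimate`, `lo`, `hi`, `z0`, `a`, `B`, `seed`,
#'   `n_failed` (resamples on which `stat_fn` was undefined).
#' @export
bca_ci <- function(stat_fn, data, B = 2000L, seed = NULL, level = 0.95) {
  if (B < 100L) stop("B must be >= 100")
  vec <- !is.data.frame(data)
  ids <- if (vec) seq_along(data) else unique(data$player_id)
  n <- length(ids)
  take <- function(sel) {
    if (vec) return(data[sel])
    rows <- unlist(lapply(sel, function(id) which(data$player_id == id)),
                   use.names = FALSE)
    data[rows, , drop = FALSE]
  }
  theta_hat <- stat_fn(if (vec) data else data)
  with_seed(seed, {
    theta_star <- vapply(seq_len(B), function(b) {
      sel <- ids[sample.int(n, n, replace = TRUE)]
      tryCatch(as.numeric(stat_fn(take(sel))), error = function(e) NA_real_)
    }, numeric(1L))
    n_failed <- sum(is.na(theta_star))
    if (n_failed > 0.05 * B)
      warning("statistic undefined on more than 5% of resamples")
    theta_star <- theta_star[!is.na(theta_star)]
    z0 <- qnorm((sum(theta_star < theta_hat) +
                   0.5 * sum(theta_star == theta_hat)) / length(theta_star))
    jack <- vapply(seq_len(n), function(i) {
      tryCatch(as.numeric(stat_fn(take(ids[-i]))), error = function(e) NA_real_)
    }, numeric(1L))
    jack <- jack[!is.na(jack)]
    dev <- mean(jack) - jack
    a <- if (sum(dev^2) == 0) 0 else sum(dev^3) / (6 * sum(dev^2)^1.5)
    ci <- bca_interval(theta_star, z0, a, level)
    list(estimate = theta_hat, lo = ci[1L], hi = ci[2L], z0 = z0, a = a,
         B = B, seed = seed, n_failed = n_failed)
  })
}

# Adjusted-percentile endpoints given bootstrap replicates and (z0, a).
bca_interval <- function(theta_star, z0, a, level = 0.95) {
  alpha <- (1 - level) / 2
  adj <- function(al) {
    z <- z0 + qnorm(al)
    pnorm(z0 + z / (1 - a * z))
  }
  unname(quantile(theta_star, probs = c(adj(alpha), adj(1 - alpha)),
                  type = 6, names = FALSE))
}

#' Map a reliability increment onto a typical baseline
#'
#' Expresses the increment `r1 -> r2` as the effective trial-count
#' multiplier implied by the Spearman-Brown relation
#' (`m = r2 (1 - r1) / (r1 (1 - r2))`) and applies that multiplier to a
#' baseline reliability (default 0.50), answering: had the measurement
#' started at the baseline, what reliability would the same amount of
#' additional trials produce? Depends only on the initial reliability and
#' how it changes.
#'
#' @param r1 Reliability before the increment (0 < r1 <= r2 < 1).
#' @param r2 Reliability after the increment.
#' @param baseline Baseline reliability to which the implied trial
#'   multiplier is applied.
#' @return The mapped reliability.
#' @export
trial_equivalent_gain <- function(r1, r2, baseline = 0.50) {
  if (!(r1 > 0 && r2 < 1)) stop("reliabilities must lie in (0, 1)")
  if (r2 < r1) stop("r2 < r1: no gain to translate")
  m <- (r2 * (1 - r1)) / (r1 * (1 - r2))
  m * baseline / (1 + (m - 1) * baseline)
}

#' Validity simulation for bootstrapping nested reliabilities
#'
#' Assesses whether the player-resampling bootstrap correctly captures the
#' joint sampling behaviour of two *nested* measurements' reliabilities
#' (measure B uses measure A's trials plus extra ones, as when
#' error-correcting responses supplement first responses). Cohorts are
#' simulated from a true-score-plus-noise model; for each cohort the
#' even-odd split-half reliability of A and B and a player bootstrap of the
#' pair are computed. The report compares the bootstrap-estimated
#' correlation between the two reliabilities (and the bootstrap SD of their
#' difference) with the true sampling values across cohorts.
#'
#' @param n_players Players per cohort.
#' @param n_trials_a Trials entering measure A.
#' @param n_extra Extra trials entering measure B on top of A's
#'   (`shared = TRUE`) or B's own independent trial count otherwise.
#' @param shared Whether B nests A's trials (the case of interest) or uses
#'   independent trials.
#' @param var_true,var_err True-score and per-trial error variances.
#' @param n_cohorts Simulated cohorts.
#' @param B Bootstrap iterations per cohort.
#' @param seed Optional seed.
#' @return List: `true_cor` (across-cohort sampling correlation of the two
#'   reliabilities), `boot_cor` (mean bootstrap estimate), `true_sd_diff`,
#'   `boot_sd_diff`, and the per-cohort `details` data.frame.
#' @export
nested_bootstrap_validity_sim <- function(n_players = 60L, n_trials_a = 40L,
                                          n_extra = 20L, shared = TRUE,
                                          var_true = 1, var_err = 4,
                                          n_cohorts = 30L, B = 200L,
                                          seed = NULL) {
  rel_split <- function(x) {
    # x: players x trials; even-odd split-half with Spearman-Brown
    nt <- ncol(x)
    o <- rowMeans(x[, seq(1L, nt, by = 2L), drop = FALSE])
    e <- rowMeans(x[, seq(2L, nt, by = 2L), drop = FALSE])
    r <- cor(o, e)
    2 * r / (1 + r)
  }
  with_seed(seed, {
    res <- lapply(seq_len(n_cohorts), function(k) {
      t_i <- rnorm(n_players, 0, sqrt(var_true))
      xa <- t_i + matrix(rnorm(n_players * n_trials_a, 0, sqrt(var_err)),
                         n_players)
      extra <- t_i + matrix(rnorm(n_players * n_extra, 0, sqrt(var_err)),
                            n_players)
      xb <- if (shared) cbind(xa, extra) else
        t_i + matrix(rnorm(n_players * (n_trials_a + n_extra), 0,
                           sqrt(var_err)), n_players)
      rel_a <- rel_split(xa); rel_b <- rel_split(xb)
      boot <- vapply(seq_len(B), function(b) {
        sel <- sample.int(n_players, n_players, replace = TRUE)
        c(rel_split(xa[sel, , drop = FALSE]), rel_split(xb[sel, , drop = FALSE]))
      }, numeric(2L))
      data.frame(rel_a = rel_a, rel_b = rel_b,
                 boot_cor = cor(boot[1L, ], boot[2L, ]),
                 boot_sd_diff = sd(boot[2L, ] - boot[1L, ]))
    })
    details <- do.call(rbind, res)
    list(true_cor = cor(details$rel_a, details$rel_b),
         boot_cor = mean(details$boot_cor),
         true_sd_diff = sd(details$rel_b - details$rel_a),
         boot_sd_diff = mean(details$boot_sd_diff),
         details = details)
  })
}
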