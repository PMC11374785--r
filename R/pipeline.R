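#' Configuration of a full analysis run
#'
#' Bundles the game configuration, population parameters, cohort sizes and
#' analysis switches for [run_pipeline()]. The default layout mirrors a
#' two-study replication design: two cohorts simulated and analysed
#' independently.
#'
#' @param n_players Players per study cohort.
#' @param n_studies Number of replicate cohorts.
#' @param game A [game_config()].
#' @param pop A [population_params()].
#' @param b_boot BCa bootstrap iterations for reliability intervals.
#' @param variant Which measurement variants to report:
#'   `"both"`, `"first_only"` or `"combined"`.
#' @param reliability_ci Compute BCa intervals around reliability estimates
#'   (the expensive stage; disable for quick structural runs).
#' @param seed Master seed; every stochastic stage derives its own child
#'   seed from it.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(n_players = 100L, n_studies = 2L,
                       game = game_config(), pop = population_params(),
                       b_boot = 500L,
                       variant = c("both", "first_only", "combined"),
                       reliability_ci = TRUE, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(n_players >= 2L, n_studies >= 1L, b_boot >= 100L,
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_players = as.integer(n_players),
                 n_studies = as.integer(n_studies),
                 game = game, pop = pop, b_boot = as.integer(b_boot),
                 variant = variant, reliability_ci = isTRUE(reliability_ci),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(lapply(unclass(config), unclass), tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-preprocess-measure-model-report pipeline
#'
#' Executes every stage for each study cohort, writing intermediate CSVs to
#' `out_dir`, and assembles a report mirroring the standard result layout:
#' trials per measurement, conflict effects per response type with CR2
#' confidence intervals, cross-response-type effect correlations,
#' reliability by measurement variant, and measurement precision. The run
#' is a pure function of the configuration: identical configs give
#' identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly; also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config, out_dir = tempdir()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  studies <- lapply(seq_len(config$n_studies), function(s) {
    run_study(config, s, out_dir)
  })
  names(studies) <- paste0("study_", seq_len(config$n_studies))
  report <- make_report(studies, config)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  invisible(report)
}

run_study <- function(config, s, out_dir) {
  tag <- paste0("study", s)
  seed <- child_seed(config$seed, 1000L + s)
  cohort <- simulate_cohort(config$pop, config$n_players, config$game, seed)
  write_session_log(cohort$trials, file.path(out_dir, paste0(tag, "_trials.csv")))
  write_truth_table(cohort$truth, file.path(out_dir, paste0(tag, "_truth.csv")))

  excl <- score_player_exclusions(cohort$trials, fps = cohort$truth[, c("player_id", "fps")])
  write.csv(excl, file.path(out_dir, paste0(tag, "_exclusions.csv")), row.names = FALSE)
  kept <- excl$player_id[!excl$excluded]
  trials <- cohort$trials[cohort$trials$player_id %in% kept, , drop = FALSE]

  responses <- extract_response_table(trials)
  f1 <- filter_trials(responses, "rt1")
  f2 <- filter_trials(f1$table, "correction")
  responses <- f2$table
  stats <- rbind(f1$stats, f2$stats)
  write.csv(stats, file.path(out_dir, paste0(tag, "_filter_stats.csv")),
            row.names = FALSE)
  tts <- filter_trials(extract_tts_table(trials), "correction")$table
  write.csv(responses, file.path(out_dir, paste0(tag, "_responses.csv")),
            row.names = FALSE, na = "")
  write.csv(tts, file.path(out_dir, paste0(tag, "_tts.csv")),
            row.names = FALSE, na = "")
  elig <- measure_eligibility(responses, tts, trials)
  write.csv(elig, file.path(out_dir, paste0(tag, "_eligibility.csv")),
            row.names = FALSE)

  ssrt <- compute_ssrt_results(trials, tts)
  write.csv(ssrt, file.path(out_dir, paste0(tag, "_ssrt.csv")), row.names = FALSE)

  analyses <- list()
  effects_tabs <- list()
  for (cf in c("flanker", "ice")) {
    ok_ids <- elig$player_id[elig[[cf]]]
    tab <- conflict_model_data(responses[responses$player_id %in% ok_ids, ], cf)
    if (length(ok_ids) >= 4L && nrow(tab)) {
      fit <- conflict_model(tab, "maximal_joint")
      eff_rt2 <- cr2_inference(fit, c(0, 1, 0, 1))   # conflict effect on RT2
      eff_diff <- cr2_inference(fit, "conflict:response")
      eff_rt1 <- cr2_inference(fit, "conflict")
      ef <- player_effects(fit)
      co <- correlate_effects(ef$effect_rt1, ef$effect_rt2)
      analyses[[cf]] <- list(
        n_players = length(ok_ids),
        effect_rt1 = cr2_row(eff_rt1), effect_rt2 = cr2_row(eff_rt2),
        rt2_minus_rt1 = cr2_row(eff_diff),
        effect_correlation = co[c("r", "ci", "t", "df", "p", "n")])
      effects_tabs[[cf]] <- ef
    } else {
      analyses[[cf]] <- list(status = "not run: too few eligible players")
    }
  }
  # TTS: flanker effect on time-to-stop and its comparison with SSRT
  ssrt_ok <- merge(ssrt, elig[elig$ssrt_tts, "player_id", drop = FALSE])
  tts_ok <- tts[tts$player_id %in% ssrt_ok$player_id, , drop = FALSE]
  if (nrow(ssrt_ok) >= 4L && nrow(tts_ok)) {
    tts_dat <- data.frame(player_id = tts_ok$player_id,
                          trial_index = tts_ok$trial_index,
                          conflict = as.numeric(tts_ok$flanker_mismatch),
                          response = 0, time = tts_ok$time,
                          condition = tts_ok$condition,
                          response_type = "correction")
    tts_fit <- conflict_model(tts_dat, "tts_model")
    tts_eff <- cr2_inference(tts_fit, "conflict")
    ssrt_fl <- ssrt_ok$ssrt_mismatch - ssrt_ok$ssrt_match
    # per-player TTS flanker effect (raw cell-mean difference) for the
    # paired comparison with the SSRT flanker effect
    agg <- aggregate(time ~ player_id + conflict, data = tts_dat, FUN = mean)
    wide <- merge(agg[agg$conflict == 1, c("player_id", "time")],
                  agg[agg$conflict == 0, c("player_id", "time")],
                  by = "player_id", suffixes = c("_mis", "_mat"))
    both <- merge(wide, data.frame(player_id = ssrt_ok$player_id, ssrt_fl = ssrt_fl))
    cmp <- tryCatch(paired_t(both$time_mis - both$time_mat, both$ssrt_fl),
                    error = function(e) list(status = "degenerate"))
    comp2 <- composite_z_average(ssrt_ok[, c("ssrt_match", "ssrt_mismatch")])
    corr_st <- correlate_effects(comp2, ssrt_ok$tts_mean)
    analyses$tts <- list(n_players = nrow(ssrt_ok),
                         flanker_effect_tts = cr2_row(tts_eff),
                         tts_vs_ssrt_diff = cmp,
                         ssrt_tts_correlation = corr_st[c("r", "ci", "t", "df", "p", "n")])
  } else {
    analyses$tts <- list(status = "not run: too few eligible players")
  }

  if (length(effects_tabs)) {
    eff_all <- do.call(rbind, Map(function(cf, ef) cbind(conflict = cf, ef),
                                  names(effects_tabs), effects_tabs))
    write.csv(eff_all, file.path(out_dir, paste0(tag, "_effects.csv")),
              row.names = FALSE)
  }

  rel <- reliability_stage(responses, ssrt_ok, elig, config)
  eta <- eta_stage(responses, tts_ok, elig)

  table1 <- trial_count_summary(responses, tts, ssrt)
  list(tag = tag, seed = seed, exclusions = excl, eligibility = elig,
       table1 = table1, analyses = analyses, reliability = rel, eta = eta)
}

cr2_row <- function(ci) {
  list(estimate = ci$estimate, se = ci$se, df = ci$df, t = ci$t, p = ci$p,
       ci = ci$ci)
}

trial_count_summary <- function(responses, tts, ssrt) {
  per_player_mean <- function(df) {
    if (!nrow(df)) return(0)
    mean(table(factor(df$player_id, levels = unique(df$player_id))))
  }
  fl <- responses[!responses$ice, , drop = FALSE]
  list(
    ice_first = per_player_mean(responses[responses$response_type == "first", ]),
    ice_corrections = per_player_mean(responses[responses$response_type == "correction", ]),
    flanker_first = per_player_mean(fl[fl$response_type == "first", ]),
    flanker_corrections = per_player_mean(fl[fl$response_type == "correction", ]),
    ssrt_lava = mean(ssrt$n_stop_match + ssrt$n_stop_mismatch),
    tts = per_player_mean(tts)
  )
}

reliability_stage <- function(responses, ssrt_ok, elig, config) {
  variants <- if (config$variant == "both") c("first_only", "combined")
              else config$variant
  out <- list()
  bseed <- child_seed(config$seed, 77L)
  for (cf in c("flanker", "ice")) {
    ids <- elig$player_id[elig[[cf]]]
    resp <- responses[responses$player_id %in% ids, , drop = FALSE]
    for (v in variants) {
      key <- paste(cf, v, sep = "_")
      out[[key]] <- tryCatch({
        r <- reliability_conflict_effect(resp, cf, v)
        if (config$reliability_ci) {
          tab <- conflict_model_data(resp, cf, include_corrections = v == "combined")
          ci <- bca_ci(function(d) {
            sh <- split_half_reliability(d, conflict_score_fn(
              if (v == "combined") "shared_conflict" else "single_response"))
            sh$r_corrected
          }, tab, B = min(config$b_boot, 500L), seed = bseed)
          r <- c(r, list(ci = c(ci$lo, ci$hi), B = ci$B))
        }
        r
      }, error = function(e) list(status = paste("not run:", conditionMessage(e))))
    }
  }
  for (v in variants) {
    key <- paste("ssrt", v, sep = "_")
    out[[key]] <- tryCatch({
      cols <- if (v == "combined") c("ssrt_match", "ssrt_mismatch", "tts_mean")
              else c("ssrt_match", "ssrt_mismatch")
      dat <- ssrt_ok[complete.cases(ssrt_ok[, cols]), , drop = FALSE]
      om <- mcdonalds_omega(dat[, cols])
      res <- list(omega = om, n_players = nrow(dat))
      if (config$reliability_ci) {
        ci <- bca_ci(function(d) mcdonalds_omega(d[, cols]), dat,
                     B = config$b_boot, seed = bseed)
        res <- c(res, list(ci = c(ci$lo, ci$hi), B = ci$B))
      }
      res
    }, error = function(e) list(status = paste("not run:", conditionMessage(e))))
  }
  out
}

eta_stage <- function(responses, tts_ok, elig) {
  out <- list()
  for (cf in c("flanker", "ice")) {
    ids <- elig$player_id[elig[[cf]]]
    resp <- responses[responses$player_id %in% ids, , drop = FALSE]
    for (rt in c("first", "correction")) {
      key <- paste0(cf, "_", if (rt == "first") "rt1" else "rt2")
      out[[key]] <- tryCatch({
        tab <- conflict_model_data(resp, cf, response_types = rt)
        fit <- conflict_model(tab, "single_response")
        precision_eta(fit, "conflict")
      }, error = function(e) NA_real_)
    }
  }
  out$tts <- tryCatch({
    if (!nrow(tts_ok)) stop("no tts")
    fit <- conflict_model(data.frame(player_id = tts_ok$player_id,
                                     conflict = as.numeric(tts_ok$flanker_mismatch),
                                     time = tts_ok$time), "tts_model")
    precision_eta(fit, "intercept")
  }, error = function(e) NA_real_)
  out
}

#' Assemble the run report
#'
#' Collects stage outputs into the final report structure (trial counts,
#' conflict effects, effect correlations, reliability, precision), with a
#' provenance block containing the config hash and seeds. Stages that did
#' not run are reported explicitly.
#'
#' @param studies List of per-study stage outputs (from [run_pipeline()]).
#' @param config The [run_config()] used.
#' @return The report list.
#' @export
make_report <- function(studies, config) {
  list(
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      n_studies = config$n_studies,
                      n_players = config$n_players,
                      package_version = as.character(utils::packageVersion("changeofmind"))),
    exclusion_counts = lapply(studies, function(s) {
      rules <- unlist(strsplit(s$exclusions$triggered_rules[s$exclusions$triggered_rules != ""], ";"))
      list(n_excluded = sum(s$exclusions$excluded),
           n_retained = sum(!s$exclusions$excluded),
           by_rule = as.list(table(rules)))
    }),
    eligibility_counts = lapply(studies, function(s)
      lapply(s$eligibility[c("flanker", "ice", "ssrt_tts")], sum)),
    table1_trials_per_measurement = lapply(studies, `[[`, "table1"),
    table2_conflict_effects = lapply(studies, `[[`, "analyses"),
    table3_reliability = lapply(studies, `[[`, "reliability"),
    table4_precision = lapply(studies, `[[`, "eta")
  )
}
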