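#' Fit a hierarchical conflict-effect model
#'
#' The central fitting function: a restricted-maximum-likelihood linear
#' mixed model of response times with the player as grouping factor and 0/1
#' treatment indicators for trial type (`conflict`; reference is the
#' non-conflict trial) and response type (`response`; reference is the
#' first response). Four variants encode different assumptions about how
#' error-correcting responses relate to initial responses:
#'
#' * `"maximal_joint"` -- fixed and random terms for intercept, trial type,
#'   response type and their interaction (maximal specification; used to
#'   estimate per-player conflict effects separately per response type).
#' * `"shared_conflict"` -- full fixed structure, random terms for
#'   intercept, trial type and response type but *not* the interaction:
#'   individual differences in the conflict effect are shared between
#'   response types (the cognitive-continuity measurement model).
#' * `"single_response"` -- fixed and random intercept and trial type, for
#'   data restricted to one response type.
#' * `"tts_model"` -- random intercept only, fixed trial type (for
#'   time-to-stop, where trial-type individual differences are minimal).
#'
#' @param data Data.frame with columns `time` (ms), `player_id`, `conflict`
#'   (0/1 or logical), and -- for the joint variants -- `response` (0/1 or
#'   logical, 1 = error-correcting response).
#' @param variant Model variant, see above.
#' @param reml Fit by REML (default) or ML.
#' @return An object of class `"conflict_model"`: a list with the `lme4`
#'   fit (`fit`), `variant`, `converged` flag, `n_obs`, `n_players`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `simulate`, `plot`, plus [player_effects()], [precision_eta()] and
#'   [cr2_inference()].
#' @seealso [simulate_measure_table()] for a matching generator.
#' @export
#' @examples
#' d <- simulate_measure_table(20, seed = 1)
#' m <- conflict_model(d, "shared_conflict")
#' coef(m)
conflict_model <- function(data,
                           variant = c("maximal_joint", "shared_conflict",
                                       "single_response", "tts_model"),
                           reml = TRUE) {
  variant <- match.arg(variant)
  need <- c("time", "player_id", "conflict")
  if (variant %in% c("maximal_joint", "shared_conflict")) need <- c(need, "response")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(data$time))) stop("outcome must be finite")
  d <- data.frame(time = data$time,
                  player = factor(data$player_id),
                  conflict = as.numeric(data$conflict))
  d$response <- if ("response" %in% names(data)) as.numeric(data$response) else 0
  if (nlevels(d$player) < 2L) stop("need at least 2 players")
  form <- switch(variant,
    maximal_joint = time ~ conflict * response + (1 + conflict * response | player),
    shared_conflict = time ~ conflict * response + (1 + conflict + response | player),
    single_response = time ~ conflict + (1 + conflict | player),
    tts_model = time ~ conflict + (1 | player))
  fit_once <- function(start = NULL) {
    withCallingHandlers(
      list(fit = lme4::lmer(form, data = d, REML = reml, start = start),
           clean = ok),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      })
  }
  ok <- TRUE
  res <- fit_once()
  if (!res$clean) {
    # one restart from mildly perturbed variance parameters, then flag
    th <- lme4::getME(res$fit, "theta")
    ok <- TRUE
    res2 <- tryCatch(fit_once(start = list(theta = th * 1.05 + 0.01)),
                     error = function(e) NULL)
    if (!is.null(res2) && res2$clean) res <- res2
  }
  structure(list(fit = res$fit, variant = variant, formula = form,
                 converged = res$clean,
                 n_obs = nrow(d), n_players = nlevels(d$player)),
            class = "conflict_model")
}

#' @export
print.conflict_model <- function(x, ...) {
  cat("Hierarchical conflict-effect model (", x$variant, ")\n", sep = "")
  cat(" players:", x$n_players, "  observations:", x$n_obs,
      if (!x$converged) "  [convergence flagged]" else "", "\n")
  fe <- lme4::fixef(x$fit)
  cat(" fixed effects (ms):\n")
  print(round(fe, 2))
  invisible(x)
}

#' @export
coef.conflict_model <- function(object, ...) lme4::fixef(object$fit)

#' @export
predict.conflict_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$fit, ...))
  nd <- data.frame(player = factor(newdata$player_id),
                   conflict = as.numeric(newdata$conflict))
  nd$response <- if ("response" %in% names(newdata)) as.numeric(newdata$response) else 0
  predict(object$fit, newdata = nd, allow.new.levels = TRUE, ...)
}

#' @export
residuals.conflict_model <- function(object, ...) resid(object$fit, ...)

#' @export
simulate.conflict_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' @export
summary.conflict_model <- function(object, cr2 = TRUE, ...) {
  vc <- lme4::VarCorr(object$fit)
  fe <- lme4::fixef(object$fit)
  tab <- if (cr2 && object$n_players >= 4L) {
    do.call(rbind, lapply(names(fe), function(nm) {
      ci <- cr2_inference(object, nm)
      data.frame(estimate = ci$estimate, se = ci$se, df = ci$df,
                 t = ci$t, p = ci$p, ci_lo = ci$ci[1L], ci_hi = ci$ci[2L],
                 row.names = nm)
    }))
  } else {
    data.frame(estimate = fe, row.names = names(fe))
  }
  out <- list(variant = object$variant, fixed = tab,
              random_sd = c(lapply(vc, function(m) attr(m, "stddev"))$player,
                            residual = sigma(object$fit)),
              converged = object$converged,
              n_obs = object$n_obs, n_players = object$n_players)
  class(out) <- "summary.conflict_model"
  out
}

#' @export
print.summary.conflict_model <- function(x, ...) {
  cat("Conflict-effect model (", x$variant, "), ",
      x$n_players, " players, ", x$n_obs, " obs\n", sep = "")
  cat("Fixed effects (CR2 cluster-robust inference):\n")
  print(round(x$fixed, 3))
  cat("Random-effect SDs (ms):\n")
  print(round(x$random_sd, 1))
  invisible(x)
}

#' @export
plot.conflict_model <- function(x, ...) {
  ef <- tryCatch(player_effects(x), error = function(e) NULL)
  if (!is.null(ef) && all(c("effect_rt1", "effect_rt2") %in% names(ef))) {
    plot(ef$effect_rt1, ef$effect_rt2,
         xlab = "conflict effect, first responses (ms)",
         ylab = "conflict effect, error corrections (ms)", ...)
    abline(0, 1, lty = 2)
  } else {
    stats::qqnorm(resid(x$fit), main = "Model residuals", ...)
    stats::qqline(resid(x$fit))
  }
  invisible(x)
}

#' Per-player conflict effects from a fitted model
#'
#' Empirical-Bayes per-player effects: the fixed effect plus the player's
#' conditional mode for the corresponding random term. For the maximal
#' joint model, `effect_rt1` is the conflict effect on first responses and
#' `effect_rt2` adds the fixed and random interaction components. The
#' `"no_pooling"` alternative refits each player separately by ordinary
#' least squares (no shrinkage).
#'
#' @param object A `conflict_model`.
#' @param method `"conditional"` (default, conditional modes) or
#'   `"no_pooling"`.
#' @return Data.frame keyed by `player_id` with `effect_rt1` and -- for
#'   joint fits -- `effect_rt2`.
#' @export
player_effects <- function(object, method = c("conditional", "no_pooling")) {
  method <- match.arg(method)
  stopifnot(inherits(object, "conflict_model"))
  d <- stats::model.frame(object$fit)
  if (method == "no_pooling") {
    joint <- object$variant %in% c("maximal_joint", "shared_conflict")
    rows <- lapply(split(d, d$player), function(s) {
      if (joint && length(unique(s$response)) > 1L) {
        cf <- coef(stats::lm(time ~ conflict * response, data = s))
        data.frame(player_id = s$player[1L], effect_rt1 = cf[["conflict"]],
                   effect_rt2 = cf[["conflict"]] + cf[["conflict:response"]])
      } else {
        cf <- coef(stats::lm(time ~ conflict, data = s))
        data.frame(player_id = s$player[1L], effect_rt1 = cf[["conflict"]])
      }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  fe <- lme4::fixef(object$fit)
  re <- lme4::ranef(object$fit)$player
  out <- data.frame(player_id = rownames(re))
  if (object$variant == "maximal_joint") {
    if (!"conflict:response" %in% colnames(re))
      stop("maximal_joint fit lacks the random interaction term")
    out$effect_rt1 <- fe[["conflict"]] + re[, "conflict"]
    out$effect_rt2 <- out$effect_rt1 + fe[["conflict:response"]] +
      re[, "conflict:response"]
  } else if (object$variant == "shared_conflict") {
    out$effect_rt1 <- fe[["conflict"]] + re[, "conflict"]
  } else if (object$variant == "single_response") {
    out$effect_rt1 <- fe[["conflict"]] + re[, "conflict"]
  } else {
    out$tts_level <- fe[["(Intercept)"]] + re[, "(Intercept)"]
  }
  out
}

#' Measurement precision of a model component
#'
#' The ratio between the standard deviation of individual differences in a
#' model component and the residual standard deviation,
#' `eta = sd(random component) / sd(residual)`. Precision governs how a
#' measurement's reliability scales with the number of trials. Use the
#' trial-type slope for conflict effects and the intercept for level
#' measures such as time-to-stop.
#'
#' @param object A `conflict_model`.
#' @param component `"conflict"` or `"intercept"`.
#' @return The precision ratio (dimensionless).
#' @export
precision_eta <- function(object, component = c("conflict", "intercept")) {
  component <- match.arg(component)
  stopifnot(inherits(object, "conflict_model"))
  sig <- sigma(object$fit)
  if (sig == 0) stop("residual SD is 0: precision undefined")
  sds <- attr(lme4::VarCorr(object$fit)$player, "stddev")
  nm <- if (component == "conflict") "conflict" else "(Intercept)"
  if (!nm %in% names(sds)) stop("component not in the random structure: ", nm)
  unname(sds[nm] / sig)
}
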