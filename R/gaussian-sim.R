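#' Simulate a measure table directly from the hierarchical model
#'
#' Generates long-format response-time observations from the Gaussian
#' hierarchical model itself (rather than from the diffusion game
#' simulator), which is the appropriate generator for parameter-recovery
#' and calibration studies of the model-fitting layer: the true fixed
#' effects, random-effect SDs and residual SD are known exactly.
#'
#' The linear predictor is
#' `time = b0 + b1*conflict + b2*response + b3*conflict:response`
#' plus player-level random effects for the same terms and iid Gaussian
#' residual noise. Indicators are 0/1 (reference: non-conflict trial, first
#' response).
#'
#' @param n_players Number of players.
#' @param n_first Length-2 counts of first-response trials per player in
#'   the (non-conflict, conflict) cells.
#' @param n_correction Length-2 counts of error-correction trials per cell
#'   (0 gives a first-responses-only table).
#' @param beta Fixed effects `c(intercept, conflict, response,
#'   interaction)` in ms.
#' @param sd_random Random-effect SDs for the same four terms (0 drops a
#'   term's player-level variability).
#' @param corr_random Optional 4x4 correlation matrix of the random
#'   effects; default identity.
#' @param sigma Residual SD (ms).
#' @param seed Optional seed.
#' @return A measure-table data.frame: `player_id`, `trial_index`,
#'   `conflict`, `response`, `time`.
#' @export
simulate_measure_table <- function(n_players,
                                   n_first = c(100L, 100L),
                                   n_correction = c(15L, 15L),
                                   beta = c(500, 50, 150, 0),
                                   sd_random = c(60, 30, 40, 0),
                                   corr_random = NULL, sigma = 120,
                                   seed = NULL) {
  stopifnot(length(beta) == 4L, length(sd_random) == 4L,
            all(sd_random >= 0), sigma >= 0)
  with_seed(seed, {
    if (is.null(corr_random)) corr_random <- diag(4L)
    S <- diag(sd_random) %*% corr_random %*% diag(sd_random)
    b <- MASS::mvrnorm(n_players, mu = rep(0, 4L), Sigma = S)
    if (n_players == 1L) b <- matrix(b, nrow = 1L)
    cells <- data.frame(
      conflict = c(0L, 1L, 0L, 1L),
      response = c(0L, 0L, 1L, 1L),
      n = c(n_first, n_correction)
    )
    rows <- lapply(seq_len(n_players), function(i) {
      cell <- cells[rep(seq_len(4L), cells$n), c("conflict", "response")]
      x <- cbind(1, cell$conflict, cell$response, cell$conflict * cell$response)
      mu <- as.vector(x %*% (beta + b[i, ]))
      data.frame(player_id = i,
                 trial_index = seq_len(nrow(cell)),
                 conflict = cell$conflict, response = cell$response,
                 time = mu + rnorm(nrow(cell), 0, sigma))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
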