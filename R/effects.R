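#' Correlate per-player effects
#'
#' Pearson correlation between two per-player measurements with the t test
#' on n-2 degrees of freedom and the Fisher-z 95% confidence interval.
#'
#' @param x,y Paired numeric vectors (pairs with missing values are
#'   dropped).
#' @param level Confidence level.
#' @return List: `r`, `ci`, `t`, `df`, `p`, `n`.
#' @export
correlate_effects <- function(x, y, level = 0.95) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, conf.level = level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       t = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, n = n)
}

#' Paired-samples t test on per-player scores
#'
#' Standard two-sided paired t test (df = n - 1). Differences with zero
#' variance are handled explicitly: identical vectors return t = 0, p = 1;
#' a constant nonzero difference is signalled as degenerate.
#'
#' @param x,y Paired numeric vectors.
#' @param level Confidence level.
#' @return List: `mean_diff`, `ci`, `t`, `df`, `p`, `n`.
#' @export
paired_t <- function(x, y, level = 0.95) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(mean_diff = 0, ci = c(0, 0), t = 0, df = n - 1L, p = 1, n = n))
    }
    stop("zero-variance nonzero differences: paired t statistic degenerate")
  }
  tt <- t.test(x, y, paired = TRUE, conf.level = level)
  list(mean_diff = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n)
}
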