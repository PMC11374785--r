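# CR2 cluster-robust variance estimation with Satterthwaite degrees of
# freedom, for OLS fits with clustered errors and for lme4 mixed models
# (clusters = players, working weights from the model-implied marginal
# covariance).
#
# Notation per cluster j: X_j (n_j x p) fixed-effect design, W_j working
# weight matrix, V_j working covariance (unit residual-variance scale),
# e_j marginal residuals, M = (sum_j X_j' W_j X_j)^{-1}.
# The CR2 adjustment A_j is the symmetric matrix satisfying
#   A_j G_j A_j = V_j  with  G_j = [(I - H) V (I - H)']_jj = V_j - X_j M X_j',
# i.e. A_j = V_j^{1/2} (V_j^{1/2} G_j V_j^{1/2})^{-1/2} V_j^{1/2}
# (the Bell-McCaffrey adjustment generalised to a GLS working model; with
# identity weights and singleton clusters it reduces exactly to HC2).
# The robust variance is M (sum_j X_j' W_j A_j e_j e_j' A_j W_j X_j) M.
#
# Satterthwaite df for a contrast c: the CR2 variance is sum_j z_j^2 with
# z_j = u_j' e-part of y, u_j = A_j W_j X_j M c. Under the working model
# z ~ N(0, Omega) with
#   Omega_jk = d_jk u_j' V_j u_k - u_j' X_j t_k - t_j' X_k' u_k
#              + t_j' M^{-1} t_k,   t_j = M X_j' u_j,
# and df = tr(Omega)^2 / tr(Omega^2).

mat_power_sym <- function(S, pow, tol = 1e-10) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  pos <- vals > tol * max(vals, tol)
  vals[pos] <- vals[pos]^pow
  vals[!pos] <- 0
  eg$vectors %*% (vals * t(eg$vectors))
}

cr2_components <- function(X_list, e_list, V_list, W_list) {
  p <- ncol(X_list[[1L]])
  Minv <- Reduce(`+`, Map(function(X, W) crossprod(X, W %*% X), X_list, W_list))
  M <- solve(Minv)
  pieces <- Map(function(X, e, V, W) {
    G <- V - X %*% M %*% t(X)
    Vh <- mat_power_sym(V, 0.5)
    A <- Vh %*% mat_power_sym(Vh %*% G %*% Vh, -0.5) %*% Vh
    WAX <- W %*% A %*% X         # n_j x p (W, A symmetric)
    list(score = crossprod(WAX, e),  # X' A W e
         WA = W %*% A, X = X, V = V)
  }, X_list, e_list, V_list, W_list)
  meat <- Reduce(`+`, lapply(pieces, function(z) tcrossprod(z$score)))
  vcov_cr2 <- M %*% meat %*% M
  list(M = M, Minv = Minv, vcov = vcov_cr2, pieces = pieces)
}

cr2_satterthwaite_df <- function(comp, cvec) {
  M <- comp$M
  Mc <- M %*% cvec
  J <- length(comp$pieces)
  u <- lapply(comp$pieces, function(z) z$WA %*% (z$X %*% Mc))  # A W X M c
  tvec <- Map(function(z, uj) M %*% crossprod(z$X, uj), comp$pieces, u)
  q1 <- mapply(function(z, uj) as.numeric(crossprod(uj, z$V %*% uj)),
               comp$pieces, u)
  Wm <- vapply(Map(function(z, uj) as.numeric(crossprod(z$X, uj)),
                   comp$pieces, u), identity, numeric(length(Mc)))
  Tm <- vapply(tvec, as.numeric, numeric(length(Mc)))
  if (is.null(dim(Wm))) { Wm <- matrix(Wm, nrow = 1L); Tm <- matrix(Tm, nrow = 1L) }
  Omega <- diag(q1, nrow = J) - crossprod(Wm, Tm) - crossprod(Tm, Wm) +
    crossprod(Tm, comp$Minv %*% Tm)
  tr1 <- sum(diag(Omega))
  tr2 <- sum(Omega * t(Omega))
  tr1^2 / tr2
}

#' CR2 cluster-robust test of a fixed-effect coefficient
#'
#' Small-sample-adjusted (CR2) cluster-robust standard error for a fixed
#' coefficient or contrast, with Satterthwaite degrees of freedom, a
#' two-sided p value and a 95% confidence interval. Clusters are players
#' for mixed models; for an `lm` fit a cluster vector must be supplied.
#' For mixed models the working weights are the inverse of the
#' model-implied marginal covariance, so the adjustment targets the same
#' covariance model the fit assumes while the meat is built from the
#' observed residuals (robust to heteroscedasticity and misspecification).
#'
#' With one observation per cluster and identity weights the CR2 standard
#' error coincides with the HC2 heteroscedasticity-robust standard error.
#'
#' @param object A [conflict_model()], an `lmerMod`, or an `lm`.
#' @param coefficient Coefficient name, or a numeric contrast vector of
#'   length p.
#' @param cluster Cluster id vector (required for `lm` objects).
#' @param level Confidence level.
#' @return A list: `estimate`, `se`, `df`, `t`, `p`, `ci` (length 2).
#' @export
cr2_inference <- function(object, coefficient, cluster = NULL, level = 0.95) {
  UseMethod("cr2_inference")
}

#' @export
cr2_inference.conflict_model <- function(object, coefficient, cluster = NULL,
                                         level = 0.95) {
  if (!object$converged)
    warning("model fit was flagged non-convergent; CR2 results may be unstable")
  cr2_inference(object$fit, coefficient, cluster = cluster, level = level)
}

#' @export
cr2_inference.lmerMod <- function(object, coefficient, cluster = NULL,
                                  level = 0.95) {
  fl <- lme4::getME(object, "flist")
  if (length(fl) != 1L)
    stop("CR2 inference supports a single grouping factor")
  grp <- fl[[1L]]
  X <- lme4::getME(object, "X")
  y <- lme4::getME(object, "y")
  beta <- lme4::fixef(object)
  e <- y - as.numeric(X %*% beta)
  Zt <- lme4::getME(object, "Zt")
  Lt <- lme4::getME(object, "Lambdat")
  LtZt <- Lt %*% Zt
  idx <- split(seq_along(grp), grp)
  if (length(idx) < 4L)
    warning("fewer than 4 clusters: CR2 inference is unreliable")
  X_list <- lapply(idx, function(i) X[i, , drop = FALSE])
  e_list <- lapply(idx, function(i) e[i])
  V_list <- lapply(idx, function(i) {
    U <- as.matrix(Matrix::t(LtZt[, i, drop = FALSE]))
    diag(length(i)) + tcrossprod(U)  # unit residual-variance scale
  })
  W_list <- lapply(V_list, solve)
  cr2_assemble(X_list, e_list, V_list, W_list, beta, coefficient, level)
}

#' @export
cr2_inference.lm <- function(object, coefficient, cluster = NULL, level = 0.95) {
  if (is.null(cluster)) stop("cluster must be supplied for lm fits")
  X <- stats::model.matrix(object)
  e <- resid(object)
  if (length(cluster) != nrow(X)) stop("cluster length must match the data")
  idx <- split(seq_len(nrow(X)), cluster)
  if (length(idx) < 4L)
    warning("fewer than 4 clusters: CR2 inference is unreliable")
  X_list <- lapply(idx, function(i) X[i, , drop = FALSE])
  e_list <- lapply(idx, function(i) e[i])
  V_list <- lapply(idx, function(i) diag(length(i)))
  cr2_assemble(X_list, e_list, V_list, V_list, coef(object), coefficient, level)
}

cr2_assemble <- function(X_list, e_list, V_list, W_list, beta, coefficient,
                         level) {
  p <- ncol(X_list[[1L]])
  if (is.character(coefficient)) {
    if (!coefficient %in% names(beta))
      stop("unknown coefficient: ", coefficient)
    cvec <- as.numeric(names(beta) == coefficient)
  } else {
    cvec <- as.numeric(coefficient)
    if (length(cvec) != p) stop("contrast length must equal ", p)
  }
  comp <- cr2_components(X_list, e_list, V_list, W_list)
  est <- sum(cvec * beta)
  se <- sqrt(as.numeric(t(cvec) %*% comp$vcov %*% cvec))
  df <- cr2_satterthwaite_df(comp, cvec)
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)
  crit <- qt(1 - (1 - level) / 2, df)
  list(estimate = est, se = se, df = df, t = tval, p = pval,
       ci = c(est - crit * se, est + crit * se))
}
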